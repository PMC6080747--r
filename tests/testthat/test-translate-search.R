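test_that("six_frame_translate matches hand translations", {
  out <- six_frame_translate(tibble::tibble(read_id = "r", sequence = "ATGGCC"))
  expect_equal(nrow(out), 6L)
  expect_equal(out$peptide[out$frame == 1L], "MA")
  # revcomp of ATGGCC is GGCCAT: GGC = G, CAT = H
  expect_equal(out$peptide[out$frame == -1L], "GH")
  expect_equal(out$peptide[out$frame == 2L], "W")  # TGG
})

test_that("translation renders stops as * and N-codons as X", {
  out <- six_frame_translate(tibble::tibble(read_id = "r",
                                            sequence = "TAAANT"))
  expect_equal(out$peptide[out$frame == 1L], "*X")
})

test_that("frame -k equals frame +k of the reverse complement", {
  withr::local_seed(21)
  reads <- tibble::tibble(
    read_id = paste0("r", 1:100),
    sequence = vapply(1:100, function(i) {
      paste(sample(c("A", "C", "G", "T"), sample(3:120, 1), replace = TRUE),
            collapse = "")
    }, character(1)))
  fwd <- six_frame_translate(reads)
  rc <- six_frame_translate(reads |>
                              dplyr::mutate(sequence = reverse_complement(sequence)))
  for (k in 1:3) {
    expect_equal(fwd$peptide[fwd$frame == -k], rc$peptide[rc$frame == k])
  }
  # length formula: |peptide| = floor((len - (|frame|-1)) / 3)
  lens <- nchar(reads$sequence)[match(fwd$read_id, reads$read_id)]
  expect_equal(nchar(fwd$peptide), (lens - (abs(fwd$frame) - 1L)) %/% 3L)
})

test_that("reads shorter than 3 nt are rejected", {
  expect_error(six_frame_translate(tibble::tibble(read_id = "r",
                                                  sequence = "AT")),
               "shorter than 3")
})

test_that("local_align reproduces matrix diagonals and handles stops", {
  # ARN self-alignment: BLOSUM62 diagonal 4 + 5 + 6
  expect_equal(local_align("ARN", "ARN")$score, 15)
  # '*' scores -4 against everything, including itself
  expect_equal(local_align("W*W", "W*W")$score, 11 - 4 + 11)
  expect_error(local_align("ABC", "ABC"), "unknown residue")
})

test_that("local_align agrees with the brute-force DP oracle", {
  mat <- mucinif:::.star_matrix("BLOSUM62")
  withr::local_seed(22)
  peps <- random_peptides(24, 2:9, alphabet = c("A", "R", "N", "D", "W"))
  pairs <- expand.grid(q = peps[1:12], t = peps[13:24],
                       stringsAsFactors = FALSE)
  for (r in sample(nrow(pairs), 40)) {
    expect_equal(local_align(pairs$q[r], pairs$t[r])$score,
                 sw_oracle(pairs$q[r], pairs$t[r], mat),
                 info = paste(pairs$q[r], pairs$t[r]))
  }
})

test_that("self-alignment dominates alignment to other targets", {
  withr::local_seed(23)
  for (i in 1:50) {
    trio <- random_peptides(2, 10:30,
                            alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
    expect_gte(local_align(trio[1], trio[1])$score,
               local_align(trio[1], trio[2])$score)
  }
})

test_that("E-values follow the closed form and scale linearly", {
  expect_equal(karlin_evalue(log2(50 * 2000), m = 50, n = 2000), 1.0)
  expect_equal(karlin_evalue(0, m = 7, n = 11), 77)
  withr::local_seed(24)
  for (i in 1:20) {
    b <- runif(1, 5, 60); m <- sample(10:100, 1); n <- sample(100:5000, 1)
    expect_equal(karlin_evalue(b, m, 2 * n), 2 * karlin_evalue(b, m, n))
    expect_gt(karlin_evalue(b, m, n), karlin_evalue(b + 1, m, n))
  }
})

test_that("screen_reads finds an exact encoded reference window", {
  fam <- fixture_family("nifH", seed = 42)
  ref_pep <- substr(fam$references$residues[1], 11, 60)  # 50-aa window
  withr::local_seed(25)
  read <- tibble::tibble(read_id = "perfect", sequence = reverse_translate(ref_pep))
  hits <- screen_reads(read, fam$references)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$family, "nifH")
  expect_lt(hits$evalue, 1e-10)
})

test_that("screen_reads handles empty inputs per contract", {
  fam <- fixture_family("nifH", seed = 42)
  none <- tibble::tibble(read_id = character(), sequence = character())
  expect_equal(nrow(screen_reads(none, fam$references)), 0L)
  bad_refs <- tibble::tibble(family = "nifH", seq_id = "x", residues = "")
  expect_error(screen_reads(none, bad_refs), "empty reference.*nifH")
})

test_that("few uniform-random reads survive the 1e-3 threshold", {
  fam <- simulate_family("nifH", seed = 77, n_members = 20,
                         n_extra_members = 0, n_decoys = 0, root_length = 80)
  withr::local_seed(26)
  reads <- tibble::tibble(
    read_id = paste0("bg", 1:1000),
    sequence = vapply(1:1000, function(i) {
      paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE), collapse = "")
    }, character(1)))
  hits <- screen_reads(reads, fam$references)
  expect_lte(length(unique(hits$read_id)), 10L)  # <= 1% of 1,000
})

test_that("screening is deterministic and one hit per read-family", {
  fam <- fixture_panel(seed = 42, families = c("nifH", "nifD"))
  srcs <- panel_sources(fam, abundance = 0.4)
  mg <- simulate_metagenome(srcs, n_reads = 40, seed = 5, read_length = 90,
                            error_rate = 0)
  refs <- panel_references(fam)
  h1 <- screen_reads(mg$reads, refs)
  h2 <- screen_reads(mg$reads[sample(nrow(mg$reads)), ], refs)
  expect_equal(h1, h2 |> dplyr::arrange(match(read_id, mg$reads$read_id), family))
  expect_false(any(duplicated(h1[c("read_id", "family")])))
})
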