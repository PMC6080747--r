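ref_aln_fixture <- function() {
  tibble::tibble(
    family = "fam",
    seq_id = c("R1", "R2", "R3"),
    aligned = c("MKVLAT-GE",
                "MKIL-TAGE",
                "MRVLASAGE"))
}

test_that("hit projection reproduces reference rows and truncations", {
  aln <- ref_aln_fixture()
  # identical to R1 ungapped -> projected row equals R1's gapped row
  expect_equal(align_hit_to_reference("MKVLATGE", aln), "MKVLAT-GE")
  # two leading residues removed -> first two non-gap columns gapped
  expect_equal(align_hit_to_reference("VLATGE", aln), "--VLAT-GE")
})

test_that("projection preserves column count for random hits", {
  fam <- fixture_family("nifD", seed = 31)
  withr::local_seed(31)
  width <- nchar(fam$alignment$aligned[1])
  for (i in 1:15) {
    src <- sample(fam$members$residues, 1)
    a <- sample(nchar(src) - 30, 1)
    hit <- substr(src, a, a + sample(15:30, 1))
    expect_equal(nchar(align_hit_to_reference(hit, fam$alignment)), width)
  }
})

test_that("unalignable hits are rejected", {
  aln <- tibble::tibble(family = "fam", seq_id = c("R1", "R2"),
                        aligned = c("AAAAAAAA", "AAAAAAGA"))
  expect_error(align_hit_to_reference("WWWW", aln),
               class = "mucinif_align_error")
})

test_that("Kimura protein distance follows the closed form", {
  expect_equal(kimura_protein_distance("ACDEF", "ACDEF"), 0)
  # p = 0.5
  expect_equal(kimura_protein_distance("ACDEFGHIKL", "ACDEFAAAAA"),
               -log(1 - 0.5 - 0.2 * 0.25), tolerance = 1e-12)
  # gapped columns are excluded
  expect_equal(kimura_protein_distance("AC-EF", "ACD-F"), 0)
  expect_warning(d <- kimura_protein_distance(strrep("A", 20), strrep("C", 20)),
                 "capped")
  expect_equal(d, 5.0)
  expect_error(kimura_protein_distance("A-", "-A"), "no shared")
})

test_that("Kimura distance increases strictly with p on [0, 0.75]", {
  L <- 100
  base <- strrep("A", L)
  p_grid <- seq(0, 0.75, by = 0.05)
  d <- vapply(p_grid, function(p) {
    other <- paste0(strrep("C", round(p * L)), strrep("A", L - round(p * L)))
    kimura_protein_distance(base, other)
  }, numeric(1))
  expect_true(all(diff(d) > 0))
})

test_that("NJ solves the three-taxon case in closed form", {
  d <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  depths <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(depths[c("A", "B", "C")], c(A = 1, B = 1, C = 2))
  expect_error(nj_tree(d[1:2, 1:2]), "at least 3")
})

test_that("NJ recovers additive matrices exactly", {
  withr::local_seed(33)
  for (i in 1:10) {
    gen <- random_additive_matrix(sample(5:9, 1))
    tr <- nj_tree(gen$d)
    expect_equal(phangorn::RF.dist(tr, gen$tree), 0)
    labs <- rownames(gen$d)
    expect_equal(ape::cophenetic.phylo(tr)[labs, labs], gen$d,
                 tolerance = 1e-9)
    expect_true(all(tr$edge.length >= 0))
  }
})

test_that("midpoint rooting equalizes the two deepest leaves", {
  tr <- midpoint_root(parse_newick("(A:1,B:3);"))
  expect_true(ape::is.rooted(tr))
  d <- ape::node.depth.edgelength(tr)
  expect_equal(d[1:2], c(2, 2))

  tr2 <- midpoint_root(parse_newick("((A:1,B:1):1,C:4);"))
  d2 <- ape::node.depth.edgelength(tr2)
  expect_equal(max(d2[1:3]), 3)
  # the two ends of the longest path are equidistant from the root
  expect_equal(sort(d2[1:3], decreasing = TRUE)[1],
               sort(d2[1:3], decreasing = TRUE)[2])
})

test_that("rerooting preserves pairwise leaf path lengths", {
  withr::local_seed(34)
  for (i in 1:10) {
    tr <- ape::rtree(sample(4:12, 1), rooted = FALSE)
    rooted <- midpoint_root(tr)
    labs <- tr$tip.label
    expect_equal(ape::cophenetic.phylo(rooted)[labs, labs],
                 ape::cophenetic.phylo(tr)[labs, labs], tolerance = 1e-9)
  }
})

test_that("zero-length trees root deterministically with a warning", {
  tr <- parse_newick("((A,B),C);")
  expect_warning(out <- midpoint_root(tr), "zero")
  expect_true(ape::is.rooted(out))
})

test_that("clade membership matches the spec's hand cases", {
  tr <- parse_newick("(((R1:1,Q:1):1,R2:2):1,OUT:3);")
  expect_true(inside_reference_clade(tr, c("R1", "R2"), "Q"))
  tr2 <- parse_newick("((R1:1,R2:1):1,(Q:1,OUT:1):1);")
  expect_false(inside_reference_clade(tr2, c("R1", "R2"), "Q"))
  expect_error(inside_reference_clade(tr, c("R1", "R2"), "nope"), "missing")
  expect_error(inside_reference_clade(tr, "R1", "Q"), "at least 2")
})

test_that("clade membership agrees with brute-force descendant enumeration", {
  withr::local_seed(35)
  for (i in 1:30) {
    n <- sample(8:24, 1)
    tr <- ape::rtree(n)
    refs <- sample(tr$tip.label, sample(2:4, 1))
    qry <- sample(setdiff(tr$tip.label, refs), 1)
    expect_equal(inside_reference_clade(tr, refs, qry),
                 descendant_oracle(tr, refs, qry))
  }
})

test_that("classify_hits confirms reference-identical hits and is order-invariant", {
  fam <- fixture_family("nifH", seed = 36)
  hits <- tibble::tibble(
    read_id = c("h1", "h2", "h3"),
    family = "nifH",
    aligned_query_peptide = c(fam$references$residues[1],
                              fam$members$residues[1],
                              substr(fam$members$residues[2], 10, 60)))
  asn <- classify_hits(hits, fam$alignment)
  expect_true(asn$inside[asn$read_id == "h1"])
  asn_rev <- classify_hits(hits[3:1, ], fam$alignment)
  expect_equal(asn, asn_rev, ignore_attr = TRUE)
  expect_error(classify_hits(hits, fam$alignment[1:2, ]), "fewer than 3")
})

test_that("decoy hits are classified outside the reference clade", {
  fam <- fixture_family("nifK", seed = 37, member_divergence = 0.3,
                        decoy_divergence = 1.5)
  hits <- tibble::tibble(
    read_id = paste0("d", seq_len(nrow(fam$decoys))),
    family = "nifK",
    aligned_query_peptide = fam$decoys$residues)
  suppressWarnings(asn <- classify_hits(hits, fam$alignment))
  expect_true(all(!asn$inside))
})
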