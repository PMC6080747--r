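# Translated homology screen: exact Smith-Waterman local alignment of
# six-frame translations against reference peptide families, with
# Karlin-Altschul E-values. This replaces a heuristic BLAST search with a
# deterministic exact aligner at the same decision threshold (E < 1e-3 for
# nif families, E < 1e-10 for the recA marker). The effective database
# length is the total residue count of the family's references, with no
# length correction.

.aa_alphabet <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X", "*")

#' Search configuration for the translated homology screen
#'
#' Defaults follow standard gapped-BLOSUM62 practice: gap open 11, gap
#' extend 1, and Karlin-Altschul constants lambda = 0.267, K = 0.041. The
#' stop character `*` scores -4 against everything (stops are kept in frame
#' and penalized, never split on).
#'
#' @param evalue_threshold Retention threshold for nif-family hits.
#' @param marker_evalue_threshold Stricter threshold used for the recA
#'   single-copy marker.
#' @param substitution_matrix Name of a Biostrings-supplied scoring matrix.
#' @param gap_open,gap_extend Affine gap penalties (a gap of length k costs
#'   `gap_open + k * gap_extend`).
#' @param lambda,K Karlin-Altschul scale and constant used to convert raw
#'   scores to bit scores.
#' @return A list of class `search_config`.
#' @export
search_config <- function(evalue_threshold = 1e-3,
                          marker_evalue_threshold = 1e-10,
                          substitution_matrix = "BLOSUM62",
                          gap_open = 11, gap_extend = 1,
                          lambda = 0.267, K = 0.041) {
  stopifnot(evalue_threshold > 0, marker_evalue_threshold > 0,
            gap_open >= gap_extend, gap_extend > 0, lambda > 0, K > 0)
  structure(list(evalue_threshold = evalue_threshold,
                 marker_evalue_threshold = marker_evalue_threshold,
                 substitution_matrix = substitution_matrix,
                 gap_open = gap_open, gap_extend = gap_extend,
                 lambda = lambda, K = K),
            class = "search_config")
}

# scoring matrix with the '*' row/column forced to -4 (including */*);
# cached, since data() is far too slow to call per alignment
.matrix_cache <- new.env(parent = emptyenv())

.star_matrix <- function(name = "BLOSUM62") {
  if (!is.null(.matrix_cache[[name]])) {
    return(.matrix_cache[[name]])
  }
  env <- new.env()
  ok <- tryCatch({
    utils::data(list = name, package = "Biostrings", envir = env)
    TRUE
  }, warning = function(w) FALSE, error = function(e) FALSE)
  if (!ok || !exists(name, envir = env)) {
    abort(sprintf("unknown substitution matrix '%s'", name),
          class = "mucinif_input_error")
  }
  m <- get(name, envir = env)
  m["*", ] <- -4L
  m[, "*"] <- -4L
  .matrix_cache[[name]] <- m
  m
}

.check_peptide <- function(x, what = "peptide") {
  pat <- "[^ACDEFGHIKLMNPQRSTVWYX*]"
  bad <- stringr::str_detect(x, pat)
  if (any(bad)) {
    ch <- stringr::str_extract(x[bad][1], pat)
    abort(sprintf("unknown residue '%s' in %s", ch, what),
          class = "mucinif_input_error")
  }
  invisible(TRUE)
}

#' Smith-Waterman local alignment of two peptides
#'
#' Optimal local alignment under the configured substitution matrix and
#' affine gap penalties. The score is never negative (an empty alignment
#' scores 0). Segment coordinates are 0-based, half-open.
#'
#' @param query,target Non-empty peptide strings over the 20 standard amino
#'   acids plus `X` and `*`.
#' @param config A [search_config()].
#' @return A list with `score`, `query_start`, `query_end`, `target_start`,
#'   `target_end`, `aligned_query`, `aligned_target` (gapped strings).
#' @export
local_align <- function(query, target, config = search_config()) {
  stopifnot(nzchar(query), nzchar(target))
  .check_peptide(query, "query")
  .check_peptide(target, "target")
  mat <- .star_matrix(config$substitution_matrix)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(target),
    type = "local", substitutionMatrix = mat,
    gapOpening = config$gap_open, gapExtension = config$gap_extend)
  s <- Biostrings::score(pa)
  if (s <= 0) {
    return(list(score = 0, query_start = 0L, query_end = 0L,
                target_start = 0L, target_end = 0L,
                aligned_query = "", aligned_target = ""))
  }
  p <- Biostrings::pattern(pa)
  t <- Biostrings::subject(pa)
  list(score = s,
       query_start = Biostrings::start(p) - 1L,
       query_end = Biostrings::end(p),
       target_start = Biostrings::start(t) - 1L,
       target_end = Biostrings::end(t),
       aligned_query = as.character(Biostrings::alignedPattern(pa)),
       aligned_target = as.character(Biostrings::alignedSubject(pa)))
}

#' Bit score from a raw alignment score
#'
#' `bit = (lambda * raw - ln K) / ln 2`.
#'
#' @param raw_score Raw Smith-Waterman score(s).
#' @param lambda,K Karlin-Altschul parameters.
#' @return Bit score(s).
#' @export
bit_score <- function(raw_score, lambda = 0.267, K = 0.041) {
  (lambda * raw_score - log(K)) / log(2)
}

#' Karlin-Altschul E-value
#'
#' `E = m * n * 2^(-bit_score)`: the expected number of chance local
#' alignments at least this strong for a query of length `m` against a
#' database of `n` residues.
#'
#' @param bit_score Bit score(s), e.g. from [bit_score()].
#' @param m Query length in residues (>= 1).
#' @param n Database length in residues (>= 1).
#' @return E-value(s).
#' @export
karlin_evalue <- function(bit_score, m, n) {
  stopifnot(all(m >= 1), all(n >= 1))
  m * n * 2^(-bit_score)
}

.as_reference_tbl <- function(references) {
  if (is.data.frame(references)) {
    ref <- as_tibble(references)
  } else {
    abort("references must be a tibble with columns family, seq_id, residues",
          class = "mucinif_input_error")
  }
  stopifnot(all(c("family", "seq_id", "residues") %in% names(ref)))
  empty <- is.na(ref$residues) | !nzchar(ref$residues)
  if (any(empty)) {
    abort(sprintf("empty reference sequence in family '%s'",
                  ref$family[empty][1]),
          class = "mucinif_input_error")
  }
  .check_peptide(ref$residues, "reference")
  ref
}

#' Screen reads against reference peptide families
#'
#' Translates every read in six frames and aligns each translation against
#' every reference peptide of every family with exact local alignment.
#' Per (read, family), only the best hit is kept (lowest E-value; ties
#' broken by higher raw score, then lexicographic reference ID), and only
#' if its E-value is below the threshold.
#'
#' @param reads Tibble with `read_id`, `sequence` (see [read_fastq()]).
#' @param references Tibble with columns `family`, `seq_id`, `residues`;
#'   every family needs at least one non-empty reference.
#' @param config A [search_config()].
#' @param evalue_threshold Retention threshold; defaults to
#'   `config$evalue_threshold`.
#' @return A tibble of family hits: `read_id`, `frame`, `family`,
#'   `reference_id`, `raw_score`, `bit_score`, `evalue`,
#'   `aligned_query_peptide` (ungapped hit segment).
#' @export
screen_reads <- function(reads, references, config = search_config(),
                         evalue_threshold = NULL) {
  ref <- .as_reference_tbl(references)
  threshold <- evalue_threshold %||% config$evalue_threshold
  empty_hits <- tibble(read_id = character(), frame = integer(),
                       family = character(), reference_id = character(),
                       raw_score = numeric(), bit_score = numeric(),
                       evalue = numeric(), aligned_query_peptide = character())
  if (nrow(reads) == 0L) {
    return(empty_hits)
  }
  pep <- six_frame_translate(reads) |> filter(nzchar(.data$peptide))
  if (nrow(pep) == 0L) {
    return(empty_hits)
  }
  mat <- .star_matrix(config$substitution_matrix)
  pep_set <- Biostrings::AAStringSet(pep$peptide)
  m_len <- nchar(pep$peptide)
  fam_split <- split(seq_len(nrow(ref)), ref$family)
  cand <- purrr::imap(fam_split, function(rows, fam) {
    n_db <- sum(nchar(ref$residues[rows]))
    per_ref <- purrr::map(rows, function(i) {
      sc <- Biostrings::pairwiseAlignment(
        pep_set, Biostrings::AAString(ref$residues[i]),
        type = "local", substitutionMatrix = mat,
        gapOpening = config$gap_open, gapExtension = config$gap_extend,
        scoreOnly = TRUE)
      sc <- pmax(sc, 0)
      tibble(pep_row = seq_len(nrow(pep)), reference_id = ref$seq_id[i],
             raw_score = sc)
    })
    bind_rows(per_ref) |>
      mutate(family = fam,
             bit_score = bit_score(.data$raw_score, config$lambda, config$K),
             evalue = karlin_evalue(.data$bit_score, m_len[.data$pep_row], n_db))
  })
  cand <- bind_rows(cand) |>
    mutate(read_id = pep$read_id[.data$pep_row],
           frame = pep$frame[.data$pep_row])
  best <- cand |>
    filter(.data$evalue < threshold) |>
    arrange(.data$read_id, .data$family, .data$evalue,
            dplyr::desc(.data$raw_score), .data$reference_id) |>
    group_by(.data$read_id, .data$family) |>
    slice(1L) |>
    ungroup()
  if (nrow(best) == 0L) {
    return(empty_hits)
  }
  segs <- purrr::map_chr(seq_len(nrow(best)), function(i) {
    al <- local_align(pep$peptide[best$pep_row[i]],
                      ref$residues[ref$seq_id == best$reference_id[i] &
                                     ref$family == best$family[i]][1],
                      config)
    gsub("-", "", al$aligned_query, fixed = TRUE)
  })
  best |>
    mutate(aligned_query_peptide = segs) |>
    select("read_id", "frame", "family", "reference_id", "raw_score",
           "bit_score", "evalue", "aligned_query_peptide") |>
    arrange(match(.data$read_id, reads$read_id), .data$family)
}
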