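# Gene-family tallies and recA normalization. Counts of clade-confirmed
# hits per nif family are divided by the count of reads matching the
# single-copy marker recA (a proxy for the number of bacterial genomes in
# the library), and the six-core-gene presence call is issued: a library is
# "complete" when homologs of all of nifH, nifD, nifK, nifE, nifN and nifB
# are detected.

#' Gene families recognized by the screen
#'
#' @return Character vector: the six core nif genes, the alternative
#'   nitrogenase subunits anfG/vnfG, and the recA marker.
#' @export
gene_families <- function() {
  c("nifH", "nifD", "nifK", "nifE", "nifN", "nifB", "anfG", "vnfG", "recA")
}

#' The six core nif genes
#'
#' The minimal diagnostic set for nitrogen-fixation capability.
#'
#' @return Character vector of length 6.
#' @export
core_nif_genes <- function() {
  c("nifH", "nifD", "nifK", "nifE", "nifN", "nifB")
}

#' Tally clade-confirmed hits per gene family
#'
#' Only assignments with `inside == TRUE` are counted; a read counts at
#' most once per family. Families with no assignments get 0.
#'
#' @param assignments Tibble from [classify_hits()].
#' @param families Families to tally (defaults to all but recA).
#' @return A tibble with columns `family` and `count`, one row per family.
#' @export
tally_assignments <- function(assignments,
                              families = setdiff(gene_families(), "recA")) {
  counted <- assignments |>
    filter(.data$inside) |>
    distinct(.data$read_id, .data$family) |>
    dplyr::count(.data$family, name = "count")
  tibble(family = families) |>
    left_join(counted, by = "family") |>
    mutate(count = as.integer(dplyr::coalesce(.data$count, 0L)))
}

#' Count reads matching the recA single-copy marker
#'
#' Runs the translated screen against the recA references at the stricter
#' marker threshold (default 1e-10). No clade step is applied to recA.
#'
#' @param reads Read tibble (see [read_fastq()]).
#' @param reca_references Tibble with `seq_id`, `residues` (a `family`
#'   column, if present, is ignored and forced to "recA").
#' @param config A [search_config()].
#' @return Integer count of distinct reads with a retained recA hit.
#' @export
count_marker <- function(reads, reca_references, config = search_config()) {
  if (nrow(reca_references) == 0L) {
    abort("empty recA reference set", class = "mucinif_input_error")
  }
  refs <- as_tibble(reca_references)
  refs$family <- "recA"
  hits <- screen_reads(reads, refs[, c("family", "seq_id", "residues")],
                       config,
                       evalue_threshold = config$marker_evalue_threshold)
  length(unique(hits$read_id))
}

#' Normalize family counts by the recA count
#'
#' @param counts Tibble with `family` and `count` (from
#'   [tally_assignments()]).
#' @param reca_count Non-negative integer.
#' @return `counts` with a `normalized` column (`count / reca_count`);
#'   when `reca_count == 0` every normalized value is `NA` and the result
#'   carries `attr(, "reca_undefined") = TRUE`.
#' @export
normalize_counts <- function(counts, reca_count) {
  stopifnot(all(counts$count >= 0))
  if (reca_count < 0) {
    abort("reca_count must be non-negative", class = "mucinif_input_error")
  }
  out <- counts |>
    mutate(normalized = if (reca_count > 0) .data$count / reca_count
           else NA_real_)
  attr(out, "reca_undefined") <- reca_count == 0
  out
}

#' Assemble a per-library nif abundance profile
#'
#' @param assignments Tibble from [classify_hits()].
#' @param reca_count recA marker count from [count_marker()].
#' @param library_id Library identifier.
#' @return A tibble of class `nif_profile` with columns `library_id`,
#'   `family`, `count`, `reca_count`, `normalized`.
#' @export
nif_profile <- function(assignments, reca_count, library_id = "library") {
  out <- tally_assignments(assignments) |>
    normalize_counts(reca_count) |>
    mutate(library_id = library_id, reca_count = as.integer(reca_count)) |>
    select("library_id", "family", "count", "reca_count", "normalized")
  class(out) <- c("nif_profile", class(out))
  out
}

#' Core nif gene presence call
#'
#' A library is called complete when all six core nif genes have at least
#' one clade-confirmed hit (the diagnostic pattern for a fixation-capable
#' community); libraries with only a subset are incomplete.
#'
#' @param profile A [nif_profile()] (or any tibble with `family`, `count`).
#' @return A list with `present` (core families with count > 0) and
#'   `complete` (logical).
#' @export
core_nif_presence <- function(profile) {
  core <- profile |>
    filter(.data$family %in% core_nif_genes(), .data$count > 0)
  present <- sort(unique(core$family))
  list(present = present, complete = length(present) == 6L)
}
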