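# Packaged isotope tables (values exactly as printed in the source field
# study): natural-abundance determinations (1A per-species/per-field means,
# 1B per-month means over two fields and two seasons) and the
# enrichment-trial table (2), used as recomputation fixtures.

.extdata <- function(name) {
  system.file("extdata", name, package = "mucinif", mustWork = TRUE)
}

#' Packaged natural-abundance table (per-species and per-field means)
#'
#' Columns: `sample`, `role` (reference/conventional/fixer), `field`,
#' `level` (species / field_mean / group_mean), `delta15n`, `sd`, `letter`.
#'
#' @return A tibble.
#' @export
bnf_table1a <- function() {
  read_plot_table(.extdata("table1a.tsv"),
                  required = c("sample", "role", "delta15n"),
                  numeric_cols = c("delta15n", "sd"))
}

#' Packaged natural-abundance time course (two fields, two seasons)
#'
#' Columns: `field`, `year`, `month` (`NA` for the season's reference-plant
#' mean), `role`, `delta15n`, `sd`, `letter`.
#'
#' @return A tibble.
#' @export
bnf_table1b <- function() {
  read_plot_table(.extdata("table1b.tsv"),
                  required = c("field", "year", "role", "delta15n"),
                  numeric_cols = c("delta15n", "sd"))
}

#' Packaged 15N-enrichment field-trial table
#'
#' One row per field x year x stage x variety with the printed values:
#' `atom15n_excess` (atom% 15N excess), `ndfa`, `shootn` (kg/ha), `ndiff`,
#' and significance flags `atom_sig`, `shootn_sig`. The isotope column is
#' treated as atom% excess (raw atom% is impossible for entries below the
#' atmospheric 0.37).
#'
#' @return A tibble.
#' @export
bnf_table2 <- function() {
  read_plot_table(.extdata("table2.tsv"),
                  required = c("field", "year", "stage", "variety", "role",
                               "atom15n_excess", "shootn"),
                  numeric_cols = c("atom15n_excess", "ndfa", "shootn",
                                   "ndiff"))
}
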