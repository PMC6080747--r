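# Orchestrators: run_nif_screen() chains screen -> classify -> tally ->
# recA normalization -> core-gene presence call; run_bnf() drives the
# isotope estimators over a plot table. Both optionally write TSV/JSON
# reports; outputs are deterministic given inputs and config.

.write_tsv <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' Run the full nif screen on one library
#'
#' Screens reads against the nif gene families, confirms hits by clade
#' membership on per-family trees, counts the recA marker at the stricter
#' threshold, normalizes, and issues the six-core-gene presence call. An
#' empty library yields an all-zero profile with the recA-undefined flag
#' and a warning rather than an error.
#'
#' @param reads Read tibble (see [read_fastq()]).
#' @param references Tibble `family`, `seq_id`, `residues` for the nif
#'   families (recA rows, if present, are routed to the marker count).
#' @param ref_alignments Tibble `family`, `seq_id`, `aligned`.
#' @param reca_references Tibble `seq_id`, `residues` for recA; defaults to
#'   the recA rows of `references`.
#' @param config A [search_config()].
#' @param library_id Library identifier.
#' @param out_dir Optional directory for TSV/newick/JSON reports.
#' @return A list of class `nif_screen`: `hits`, `assignments`, `profile`
#'   ([nif_profile()]), `trees`, `presence`, `summary`.
#' @export
run_nif_screen <- function(reads, references, ref_alignments,
                           reca_references = NULL,
                           config = search_config(),
                           library_id = "library", out_dir = NULL) {
  references <- .as_reference_tbl(references)
  if (is.null(reca_references)) {
    reca_references <- references |> filter(.data$family == "recA")
  }
  nif_refs <- references |> filter(.data$family != "recA")
  if (nrow(reads) == 0L) {
    warn(sprintf("library '%s' has no reads: returning all-zero profile",
                 library_id))
    assignments <- tibble(read_id = character(), family = character(),
                          inside = logical(), n_shared_columns = integer())
    profile <- nif_profile(assignments, reca_count = 0,
                           library_id = library_id)
    hits <- screen_reads(reads, nif_refs, config)
    trees <- list()
  } else {
    hits <- screen_reads(reads, nif_refs, config)
    assignments <- classify_hits(hits, ref_alignments, config)
    trees <- attr(assignments, "trees")
    reca_count <- if (nrow(reca_references) > 0L) {
      count_marker(reads, reca_references, config)
    } else 0L
    profile <- nif_profile(assignments, reca_count, library_id = library_id)
  }
  presence <- core_nif_presence(profile)
  summary <- list(
    library_id = library_id,
    n_reads = nrow(reads),
    n_hits = nrow(hits),
    n_inside = sum(assignments$inside),
    reca_count = unique(profile$reca_count),
    reca_undefined = isTRUE(attr(
      normalize_counts(profile[, c("family", "count")],
                       unique(profile$reca_count)), "reca_undefined")),
    present = as.list(presence$present),
    complete = presence$complete,
    config = list(evalue_threshold = config$evalue_threshold,
                  marker_evalue_threshold = config$marker_evalue_threshold,
                  substitution_matrix = config$substitution_matrix,
                  gap_open = config$gap_open, gap_extend = config$gap_extend,
                  lambda = config$lambda, K = config$K))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    .write_tsv(hits, file.path(out_dir, "hits.tsv"))
    .write_tsv(as_tibble(assignments), file.path(out_dir, "assignments.tsv"))
    .write_tsv(as_tibble(profile), file.path(out_dir, "profile.tsv"))
    if (length(trees) > 0L) {
      tree_dir <- file.path(out_dir, "trees")
      dir.create(tree_dir, showWarnings = FALSE)
      purrr::iwalk(trees, function(tr, fam) {
        write_newick(tr, file.path(tree_dir, paste0(fam, ".nwk")))
      })
    }
    .write_json(summary, file.path(out_dir, "summary.json"))
  }
  structure(list(hits = hits, assignments = assignments, profile = profile,
                 trees = trees, presence = presence, summary = summary),
            class = "nif_screen")
}

#' @export
print.nif_screen <- function(x, ...) {
  cat(sprintf("nif screen of library '%s': %d reads, %d hits, %d inside clade\n",
              x$summary$library_id, x$summary$n_reads, x$summary$n_hits,
              x$summary$n_inside))
  cat(sprintf("recA count: %d; core nif genes present: %d/6; complete: %s\n",
              x$summary$reca_count, length(x$presence$present),
              x$presence$complete))
  invisible(x)
}

#' Run the BNF estimators over a plot table
#'
#' @param table A plot-level tibble or a path to a delimited table (read
#'   with [read_plot_table()]).
#' @param mode `"natural"` or `"enrichment"`.
#' @param config A [bnf_config()].
#' @param by Grouping columns (see [estimate_bnf()]).
#' @param out_dir Optional directory for TSV/JSON reports.
#' @return A list of class `bnf_run`: `analysis` (the [estimate_bnf()]
#'   object) and `summary` (includes the min-max range of estimates).
#' @export
run_bnf <- function(table, mode = c("natural", "enrichment"),
                    config = bnf_config(),
                    by = NULL, out_dir = NULL) {
  mode <- match.arg(mode)
  if (is.character(table) && length(table) == 1L) {
    value_col <- if (mode == "natural") "delta15n" else "atom15n_excess"
    table <- read_plot_table(table, required = c("variety", "role", value_col),
                             numeric_cols = value_col)
  }
  if (is.null(by)) by <- intersect(c("field", "year", "stage"), names(table))
  fit <- estimate_bnf(table, mode = mode, config = config, by = by)
  est <- fit$estimates
  summary <- list(
    mode = mode,
    ndiff_denominator = config$ndiff_denominator,
    n_estimates = nrow(est),
    n_out_of_range = sum(est$out_of_range, na.rm = TRUE),
    ndfa_range = as.list(round(range(est$ndfa_percent, na.rm = TRUE), 1)),
    ndiff_range = if (any(!is.na(est$ndiff_percent))) {
      as.list(round(range(est$ndiff_percent, na.rm = TRUE), 1))
    } else NULL,
    correlations = if (!is.null(fit$correlations)) {
      purrr::transpose(as.list(fit$correlations))
    } else NULL)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    .write_tsv(est, file.path(out_dir, "estimates.tsv"))
    if (!is.null(fit$correlations)) {
      .write_tsv(fit$correlations, file.path(out_dir, "correlations.tsv"))
    }
    .write_json(summary, file.path(out_dir, "summary.json"))
  }
  structure(list(analysis = fit, summary = summary), class = "bnf_run")
}

#' @export
print.bnf_run <- function(x, ...) {
  print(x$analysis)
  invisible(x)
}
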