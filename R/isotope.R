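# Estimators for the percentage of plant nitrogen derived from the
# atmosphere (%Ndfa) and the nitrogen-difference estimate (%Ndiff), over
# plot-level field-trial tables.
#
# Natural abundance: %Ndfa = 100 * (d15N_ref - d15N_fixer) / (d15N_ref - B),
# with B the 15N abundance of air-derived N in the plant (0.0 permil here).
# Enrichment:        %Ndfa = 100 * (1 - excess_fixer / excess_reference),
# where atom% 15N excess = measured atom% - 0.37 (air).
# N difference:      %Ndiff = 100 * (N_fixer - N_ref) / denominator,
# denominator either the reference shoot N (formula as printed) or the
# fixer shoot N (the variant consistent with the published table values).
#
# Estimates are never clamped: values outside [0, 100] are returned as-is
# and flagged.

#' Decimal half-up rounding
#'
#' Rounds the way printed tables are rounded (0.5 always away from zero, on
#' the decimal value), unlike [round()], which is IEEE round-half-even on
#' the binary representation. A small epsilon guards against values such as
#' `2.705` being stored as `2.70499...`.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

#' Configuration for the BNF estimators
#'
#' @param B 15N abundance (permil) of plant N derived from air; default 0.
#' @param air_atom_percent Atmospheric 15N atom percent subtracted to form
#'   atom% excess; default 0.37.
#' @param ndiff_denominator `"reference"` (the printed formula) or
#'   `"fixer"` (the variant consistent with the published table).
#' @return A list of class `bnf_config`.
#' @export
bnf_config <- function(B = 0, air_atom_percent = 0.37,
                       ndiff_denominator = c("reference", "fixer")) {
  stopifnot(is.finite(B), air_atom_percent > 0, air_atom_percent < 1)
  structure(list(B = B, air_atom_percent = air_atom_percent,
                 ndiff_denominator = match.arg(ndiff_denominator)),
            class = "bnf_config")
}

#' %Ndfa by 15N natural abundance
#'
#' `100 * (delta_ref - delta_fix) / (delta_ref - B)`. Out-of-range values
#' are returned unclamped (see [estimate_bnf()] for flagging).
#'
#' @param delta_ref Reference-plant delta 15N (permil).
#' @param delta_fix Fixer-candidate delta 15N (permil).
#' @param B Baseline for fully air-derived N (permil).
#' @return Percent Ndfa (vectorized).
#' @export
ndfa_natural_abundance <- function(delta_ref, delta_fix, B = 0) {
  if (any(delta_ref == B)) {
    abort("degenerate baseline: delta_ref equals B",
          class = "mucinif_input_error")
  }
  100 * (delta_ref - delta_fix) / (delta_ref - B)
}

#' Atom percent 15N excess
#'
#' Measured atom% 15N minus the atmospheric background. Negative excess is
#' allowed (and should be flagged downstream).
#'
#' @param atom_percent Measured atom% 15N (>= 0).
#' @param air_atom_percent Atmospheric background, default 0.37.
#' @return Atom% excess (vectorized).
#' @export
atom_percent_excess <- function(atom_percent, air_atom_percent = 0.37) {
  stopifnot(all(atom_percent >= 0))
  atom_percent - air_atom_percent
}

#' %Ndfa by 15N enrichment (isotope dilution)
#'
#' `100 * (1 - excess_fixer / excess_reference)`, unclamped.
#'
#' @param excess_fixer Fixer-candidate atom% 15N excess.
#' @param excess_reference Reference atom% 15N excess (nonzero).
#' @return Percent Ndfa (vectorized).
#' @export
ndfa_enrichment <- function(excess_fixer, excess_reference) {
  if (any(excess_reference == 0)) {
    abort("reference atom% excess is zero", class = "mucinif_input_error")
  }
  100 * (1 - excess_fixer / excess_reference)
}

#' %Ndiff: nitrogen-difference estimate of fixation
#'
#' @param n_fixer,n_reference Shoot N (kg/ha) of fixer and reference.
#' @param denominator `"reference"`: `100 * (Nf - Nr) / Nr` (formula as
#'   printed); `"fixer"`: `100 * (Nf - Nr) / Nf` (table-consistent
#'   variant).
#' @return Percent Ndiff (vectorized).
#' @export
ndiff <- function(n_fixer, n_reference,
                  denominator = c("reference", "fixer")) {
  denominator <- match.arg(denominator)
  den <- if (denominator == "reference") n_reference else n_fixer
  if (any(den == 0)) {
    abort("zero denominator in %Ndiff", class = "mucinif_input_error")
  }
  100 * (n_fixer - n_reference) / den
}

#' Per-group arithmetic mean of reference records
#'
#' Averages a value column within groups (e.g. the mean of the two
#' reference varieties per field/year/stage, used as the baseline for
#' %Ndfa and %Ndiff).
#'
#' @param records A data frame of the records to average.
#' @param value Name of the value column.
#' @param by Character vector of grouping columns (may be empty).
#' @return A tibble of group keys plus `reference_value`.
#' @export
reference_mean <- function(records, value, by = character()) {
  stopifnot(value %in% names(records))
  records <- as_tibble(records)
  out <- records |>
    group_by(across(dplyr::all_of(by))) |>
    summarise(n_reference = sum(!is.na(.data[[value]])),
              reference_value = mean(.data[[value]], na.rm = TRUE),
              .groups = "drop")
  if (any(out$n_reference == 0L)) {
    bad <- out |> filter(.data$n_reference == 0L)
    key <- if (length(by) > 0L) {
      paste(unlist(bad[1, by]), collapse = "/")
    } else "(all)"
    abort(sprintf("group %s has no reference records", key),
          class = "mucinif_input_error")
  }
  out |> select(-"n_reference")
}

#' Pooled-variance two-sample t test
#'
#' Textbook pooled two-sample t statistic with a two-sided p-value. When
#' both groups have zero variance and equal means, the convention t = 0,
#' p = 1 is returned.
#'
#' @param values_a,values_b Numeric vectors, each of length >= 2.
#' @return A list with `t`, `df`, `p_value`.
#' @export
group_compare <- function(values_a, values_b) {
  na <- length(values_a)
  nb <- length(values_b)
  if (na < 2L || nb < 2L) {
    abort("each group needs at least 2 values", class = "mucinif_input_error")
  }
  sp2 <- ((na - 1) * stats::var(values_a) + (nb - 1) * stats::var(values_b)) /
    (na + nb - 2)
  diff <- mean(values_a) - mean(values_b)
  df <- na + nb - 2
  if (sp2 == 0) {
    if (diff == 0) return(list(t = 0, df = df, p_value = 1))
    return(list(t = sign(diff) * Inf, df = df, p_value = 0))
  }
  t <- diff / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}

#' Single-degree-of-freedom contrast: one test group vs reference mean
#'
#' Compares the mean of one test variety to the unweighted mean of the
#' reference varieties' means, using the error variance pooled across all
#' groups.
#'
#' @param test_values Numeric vector for the test variety (length >= 2).
#' @param reference_groups List of numeric vectors, one per reference
#'   variety (each length >= 2).
#' @return A list with `t`, `df`, `p_value`, `estimate` (the contrast).
#' @export
contrast_compare <- function(test_values, reference_groups) {
  groups <- c(list(test_values), reference_groups)
  if (any(lengths(groups) < 2L)) {
    abort("each group needs at least 2 values", class = "mucinif_input_error")
  }
  k <- length(reference_groups)
  ss <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df <- sum(lengths(groups)) - length(groups)
  mse <- ss / df
  est <- mean(test_values) -
    mean(vapply(reference_groups, mean, numeric(1)))
  coef_sq <- 1 / length(test_values) +
    sum(vapply(reference_groups, function(g) (1 / k)^2 / length(g),
               numeric(1)))
  if (mse == 0) {
    if (est == 0) return(list(t = 0, df = df, p_value = 1, estimate = 0))
    return(list(t = sign(est) * Inf, df = df, p_value = 0, estimate = est))
  }
  t <- est / sqrt(mse * coef_sq)
  list(t = t, df = df, p_value = 2 * stats::pt(-abs(t), df), estimate = est)
}

#' Pearson correlation between %Ndfa and %Ndiff
#'
#' @param estimates A data frame with `ndfa_percent` and `ndiff_percent`
#'   columns (e.g. from [estimate_bnf()]).
#' @param by Optional grouping column (e.g. `"year"`).
#' @return A tibble with group keys, `n`, `r` and `p_value`. Groups with
#'   zero variance in either vector get `r = NA` with a warning.
#' @export
ndfa_ndiff_correlation <- function(estimates, by = character()) {
  estimates <- as_tibble(estimates) |>
    filter(!is.na(.data$ndfa_percent), !is.na(.data$ndiff_percent))
  one <- function(d) {
    if (nrow(d) < 3L) {
      abort("need at least 3 paired estimates", class = "mucinif_input_error")
    }
    if (stats::sd(d$ndfa_percent) == 0 || stats::sd(d$ndiff_percent) == 0) {
      warn("zero variance: correlation undefined")
      return(tibble(n = nrow(d), r = NA_real_, p_value = NA_real_))
    }
    ct <- stats::cor.test(d$ndfa_percent, d$ndiff_percent)
    tibble(n = nrow(d), r = unname(ct$estimate), p_value = ct$p.value)
  }
  if (length(by) == 0L) {
    return(one(estimates))
  }
  estimates |>
    group_by(across(dplyr::all_of(by))) |>
    dplyr::group_modify(~ one(.x)) |>
    ungroup()
}

#' Estimate biological nitrogen fixation from a plot-level table
#'
#' The driver for both isotope-dilution estimators. The input table has one
#' row per plot (or per printed variety mean) with a `role` column marking
#' `"reference"` vs `"fixer"` rows and a `variety` column. Per group
#' (default: every combination of `field`, `year`, `stage` present in the
#' table) the reference baseline is the mean over reference records; each
#' fixer variety then gets %Ndfa (from `delta15n` in natural mode or
#' `atom15n_excess` in enrichment mode), %Ndiff when a `shootn` column is
#' present, an out-of-range flag, and a single-degree-of-freedom contrast
#' p-value when plot-level replicates allow one.
#'
#' @param table Plot-level tibble (see [read_plot_table()]).
#' @param mode `"natural"` or `"enrichment"`.
#' @param config A [bnf_config()].
#' @param by Grouping columns; defaults to those of `field`, `year`,
#'   `stage` present in the table.
#' @return An object of class `bnf_analysis`: a list with `estimates`
#'   (tibble), `correlations` (tibble or NULL), `mode`, `config`.
#'   See [tidy()], [glance()], [autoplot()].
#' @export
estimate_bnf <- function(table, mode = c("natural", "enrichment"),
                         config = bnf_config(),
                         by = intersect(c("field", "year", "stage"),
                                        names(table))) {
  mode <- match.arg(mode)
  table <- as_tibble(table)
  value_col <- if (mode == "natural") "delta15n" else "atom15n_excess"
  required <- c("variety", "role", value_col)
  missing <- setdiff(required, names(table))
  if (length(missing) > 0L) {
    abort(sprintf("missing required column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "mucinif_schema_error")
  }
  has_shootn <- "shootn" %in% names(table)
  ref_tbl <- reference_mean(table |> filter(.data$role == "reference"),
                            value_col, by)
  ref_n <- if (has_shootn) {
    reference_mean(table |> filter(.data$role == "reference"),
                   "shootn", by) |>
      dplyr::rename(reference_shootn = "reference_value")
  } else NULL
  fixers <- table |> filter(.data$role == "fixer")
  key_join <- function(x, y) {
    if (length(by) == 0L) dplyr::cross_join(x, y) else
      left_join(x, y, by = by)
  }
  est <- fixers |>
    group_by(across(dplyr::all_of(c(by, "variety")))) |>
    summarise(n_plots = sum(!is.na(.data[[value_col]])),
              value_fixer = mean(.data[[value_col]], na.rm = TRUE),
              shootn_fixer = if (has_shootn)
                mean(.data$shootn, na.rm = TRUE) else NA_real_,
              .groups = "drop") |>
    key_join(ref_tbl)
  if (!is.null(ref_n)) est <- key_join(est, ref_n)
  est <- est |>
    mutate(ndfa_percent = if (mode == "natural") {
      ndfa_natural_abundance(.data$reference_value, .data$value_fixer,
                             config$B)
    } else {
      ndfa_enrichment(.data$value_fixer, .data$reference_value)
    },
    ndiff_percent = if (has_shootn) {
      ndiff(.data$shootn_fixer, .data$reference_shootn,
            config$ndiff_denominator)
    } else NA_real_,
    out_of_range = .data$ndfa_percent < 0 | .data$ndfa_percent > 100)
  # contrast p-values where plot-level replication allows them
  est$p_value <- purrr::pmap_dbl(est[c(by, "variety")], function(...) {
    key <- list(...)
    sel <- rep(TRUE, nrow(table))
    for (k in setdiff(names(key), "variety")) {
      sel <- sel & !is.na(table[[k]]) & table[[k]] == key[[k]]
    }
    grp <- table[sel, ]
    tv <- grp[[value_col]][grp$role == "fixer" & grp$variety == key$variety]
    tv <- tv[!is.na(tv)]
    refs <- grp |> filter(.data$role == "reference")
    ref_groups <- split(refs[[value_col]], refs$variety)
    ref_groups <- lapply(ref_groups, function(v) v[!is.na(v)])
    if (length(tv) < 2L || length(ref_groups) == 0L ||
        any(lengths(ref_groups) < 2L)) {
      return(NA_real_)
    }
    contrast_compare(tv, ref_groups)$p_value
  })
  corr <- NULL
  ok <- !is.na(est$ndfa_percent) & !is.na(est$ndiff_percent)
  if (sum(ok) >= 3L) {
    corr_by <- intersect("year", by)
    corr <- tryCatch(ndfa_ndiff_correlation(est[ok, ], by = corr_by),
                     error = function(e) NULL)
  }
  structure(list(estimates = est, correlations = corr, mode = mode,
                 config = config, by = by),
            class = "bnf_analysis")
}

#' @export
print.bnf_analysis <- function(x, ...) {
  cat(sprintf("BNF analysis (%s 15N mode, ndiff denominator: %s)\n",
              x$mode, x$config$ndiff_denominator))
  cat(sprintf("%d estimates across %d group column(s)\n",
              nrow(x$estimates), length(x$by)))
  rng <- range(x$estimates$ndfa_percent, na.rm = TRUE)
  cat(sprintf("%%Ndfa range: %.1f to %.1f\n", rng[1], rng[2]))
  if (any(!is.na(x$estimates$ndiff_percent))) {
    rng <- range(x$estimates$ndiff_percent, na.rm = TRUE)
    cat(sprintf("%%Ndiff range: %.1f to %.1f\n", rng[1], rng[2]))
  }
  invisible(x)
}
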