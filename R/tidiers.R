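# broom-style accessors and ggplot2 autoplot methods for the two result
# types.

#' Tidy a BNF analysis into its estimates table
#'
#' @param x A `bnf_analysis` from [estimate_bnf()].
#' @param ... Unused.
#' @return The estimates tibble (one row per group x fixer variety).
#' @export
tidy.bnf_analysis <- function(x, ...) {
  as_tibble(x$estimates)
}

#' One-row summary of a BNF analysis
#'
#' @param x A `bnf_analysis` from [estimate_bnf()].
#' @param ... Unused.
#' @return A one-row tibble with the estimate counts and ranges.
#' @export
glance.bnf_analysis <- function(x, ...) {
  est <- x$estimates
  has_ndiff <- any(!is.na(est$ndiff_percent))
  tibble(mode = x$mode,
         n_estimates = nrow(est),
         n_out_of_range = sum(est$out_of_range, na.rm = TRUE),
         ndfa_min = min(est$ndfa_percent, na.rm = TRUE),
         ndfa_max = max(est$ndfa_percent, na.rm = TRUE),
         ndiff_min = if (has_ndiff) min(est$ndiff_percent, na.rm = TRUE)
           else NA_real_,
         ndiff_max = if (has_ndiff) max(est$ndiff_percent, na.rm = TRUE)
           else NA_real_)
}

#' @rdname tidy.bnf_analysis
#' @export
tidy.bnf_run <- function(x, ...) tidy(x$analysis)

#' @rdname glance.bnf_analysis
#' @export
glance.bnf_run <- function(x, ...) glance(x$analysis)

#' Plot a nif abundance profile
#'
#' Bar chart of recA-normalized abundance per gene family (counts are shown
#' when normalization is undefined).
#'
#' @param object A [nif_profile()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nif_profile <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(family = factor(.data$family, levels = gene_families()))
  use_norm <- any(!is.na(df$normalized))
  y <- if (use_norm) "normalized" else "count"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$family, y = .data[[y]],
                                   fill = .data$library_id)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL,
                  y = if (use_norm) "hits / recA hit" else "clade-confirmed hits",
                  fill = "library") +
    ggplot2::theme_minimal()
}

#' Plot a BNF analysis
#'
#' %Ndfa per fixer variety and group, with out-of-range estimates marked.
#'
#' @param object A `bnf_analysis` from [estimate_bnf()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bnf_analysis <- function(object, ...) {
  est <- object$estimates
  grp <- intersect(c("field", "year", "stage"), names(est))
  est$group <- if (length(grp) > 0L) {
    do.call(paste, c(est[grp], sep = "/"))
  } else ""
  ggplot2::ggplot(est, ggplot2::aes(x = .data$group, y = .data$ndfa_percent,
                                    fill = .data$variety)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_point(data = est[est$out_of_range, , drop = FALSE],
                        position = ggplot2::position_dodge(width = 0.9),
                        shape = 8, show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "%Ndfa",
                  title = sprintf("%s 15N estimates", object$mode)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname autoplot.bnf_analysis
#' @export
autoplot.bnf_run <- function(object, ...) autoplot(object$analysis)
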