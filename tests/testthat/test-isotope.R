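test_that("natural-abundance %Ndfa follows the isotope-dilution formula", {
  # printed per-table means: reference 5.42, landrace 2.71, B = 0
  expect_equal(ndfa_natural_abundance(5.42, 2.71, B = 0), 50.0)
  expect_equal(ndfa_natural_abundance(4, 4), 0)
  expect_equal(ndfa_natural_abundance(4, 0), 100)
  expect_error(ndfa_natural_abundance(0, 1, B = 0), "degenerate")
  # linear in delta_fix at fixed baseline
  d <- seq(-2, 6, by = 0.5)
  v <- ndfa_natural_abundance(6, d)
  expect_equal(diff(v), rep(v[2] - v[1], length(d) - 1))
  # delta_fix within [B, delta_ref] keeps estimates in [0, 100]
  expect_true(all(ndfa_natural_abundance(6, seq(0, 6, 0.5)) >= 0))
  expect_true(all(ndfa_natural_abundance(6, seq(0, 6, 0.5)) <= 100))
})

test_that("atom percent excess subtracts the air background", {
  expect_equal(atom_percent_excess(0.37), 0)
  expect_equal(atom_percent_excess(1.37), 1)
  x <- c(0.4, 0.9, 2.1)
  expect_equal(atom_percent_excess(x + 0.05), atom_percent_excess(x) + 0.05)
})

test_that("enrichment %Ndfa follows the dilution ratio", {
  # Field 5, Tassel: fixer excess 0.08 vs reference 0.18
  expect_equal(round(ndfa_enrichment(0.08, 0.18), 1), 55.6)
  expect_equal(ndfa_enrichment(0.2, 0.2), 0)
  expect_equal(ndfa_enrichment(0, 0.2), 100)
  expect_error(ndfa_enrichment(0.1, 0), "zero")
})

test_that("%Ndiff supports both denominators", {
  expect_equal(ndiff(10, 10, "reference"), 0)
  expect_equal(ndiff(10, 10, "fixer"), 0)
  # Field 5 Tassel shoot N: fixer 61.4 vs reference 9.8
  expect_equal(round(ndiff(61.4, 9.8, "reference"), 1), 526.5)
  expect_equal(round(ndiff(61.4, 9.8, "fixer"), 1), 84.0)
  expect_error(ndiff(1, 0, "reference"), "zero")
})

test_that("reference_mean averages per group and flags empty groups", {
  expect_equal(reference_mean(tibble::tibble(v = c(4, 6)), "v")$reference_value,
               5)
  expect_equal(reference_mean(tibble::tibble(v = 7), "v")$reference_value, 7)
  tbl <- tibble::tibble(g = c("a", "a", "b"), v = c(1, 3, NA))
  expect_error(reference_mean(tbl, "v", by = "g"), "group b")
  # the two landrace field means average to the printed landrace mean
  t1a <- bnf_table1a()
  fields <- dplyr::filter(t1a, level == "field_mean")
  expect_equal(round_half_up(reference_mean(fields, "delta15n")$reference_value,
                             2),
               2.71)
})

test_that("pooled t test matches the hand formula and t.test", {
  out <- group_compare(c(1, 2, 3), c(4, 5, 6))
  expect_equal(abs(out$t), 3.674, tolerance = 1e-3)
  ref <- stats::t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)
  expect_equal(out$t, unname(ref$statistic))
  expect_equal(out$p_value, ref$p.value)
  # symmetry and the degenerate conventions
  swapped <- group_compare(c(4, 5, 6), c(1, 2, 3))
  expect_equal(swapped$p_value, out$p_value)
  same <- group_compare(c(2, 2), c(2, 2))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  expect_error(group_compare(1, c(1, 2)), "at least 2")
})

test_that("single-df contrast reduces to the pooled t with one reference", {
  a <- c(1.2, 0.8, 1.5, 0.9)
  b <- c(2.2, 1.9, 2.6, 2.4)
  expect_equal(contrast_compare(a, list(b))$t, group_compare(a, b)$t)
  # against the textbook contrast formula with two reference groups
  r1 <- c(2, 3, 2.5); r2 <- c(4, 5, 4.5)
  out <- contrast_compare(a, list(r1, r2))
  groups <- list(a, r1, r2)
  mse <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1))) /
    (sum(lengths(groups)) - 3)
  est <- mean(a) - mean(c(mean(r1), mean(r2)))
  se <- sqrt(mse * (1 / 4 + 0.25 / 3 + 0.25 / 3))
  expect_equal(out$t, est / se)
})

test_that("Ndfa-Ndiff correlation matches the direct formula", {
  lin <- tibble::tibble(ndfa_percent = 1:10, ndiff_percent = 2 * (1:10) + 3)
  expect_equal(ndfa_ndiff_correlation(lin)$r, 1)
  anti <- tibble::tibble(ndfa_percent = 1:10, ndiff_percent = -(1:10))
  expect_equal(ndfa_ndiff_correlation(anti)$r, -1)
  withr::local_seed(61)
  x <- rnorm(30); y <- 0.5 * x + rnorm(30)
  tbl <- tibble::tibble(ndfa_percent = x, ndiff_percent = y)
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(ndfa_ndiff_correlation(tbl)$r, r_direct)
  flat <- tibble::tibble(ndfa_percent = rep(1, 5), ndiff_percent = 1:5)
  expect_warning(out <- ndfa_ndiff_correlation(flat), "zero variance")
  expect_true(is.na(out$r))
})

test_that("estimate_bnf recomputes the enrichment table from its cells", {
  t2 <- bnf_table2()
  fit <- estimate_bnf(t2, mode = "enrichment",
                      config = bnf_config(ndiff_denominator = "fixer"))
  est <- tidy(fit)
  f5 <- dplyr::filter(est, field == 5, year == 2016, stage == "Tassel",
                      variety == "SM1")
  expect_equal(round(f5$ndfa_percent, 1), 55.6)
  expect_equal(round(f5$ndiff_percent, 1), 84.0)
  expect_false(f5$out_of_range)
  g <- glance(fit)
  expect_equal(g$n_estimates, 23L)
  expect_equal(g$mode, "enrichment")
})

test_that("noise-free natural and enrichment runs agree exactly with truth", {
  for (mode in c("natural", "enrichment")) {
    tr <- simulate_field_trial(seed = 62, mode = mode, noise_sd = 0)
    fit <- estimate_bnf(tr$plots, mode = mode,
                        config = bnf_config(ndiff_denominator = "fixer"))
    expect_equal(fit$estimates$ndfa_percent, c(40, 40), tolerance = 1e-10)
    expect_equal(fit$estimates$ndiff_percent, c(40, 40), tolerance = 1e-10)
  }
})

test_that("negative reference-period delta15n drives %Ndfa out of range", {
  # the 2012 Field 2 pattern: fixer delta below zero with a positive
  # reference baseline gives estimates above 100, flagged but unclamped
  tbl <- tibble::tibble(
    variety = c("ref1", "ref2", "SM"), role = c("reference", "reference",
                                                "fixer"),
    delta15n = c(2.9, 2.54, -1.02))
  fit <- estimate_bnf(tbl, mode = "natural")
  expect_gt(fit$estimates$ndfa_percent, 100)
  expect_true(fit$estimates$out_of_range)
})
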