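test_that("binning sorts by fraction, averages equal bins, and preserves
           the grand mean", {
  set.seed(10)
  rec <- data.frame(fraction = runif(30, 0.01, 0.3),
                    E_kpa = runif(30, 0.2, 4))
  b <- bin_cells(rec, 10)
  expect_identical(nrow(b), 3L)
  expect_true(all(diff(b$fraction) > 0))
  expect_equal(mean(b$E_kpa), mean(rec$E_kpa))
  expect_error(bin_cells(rec[1:5, ], 10), "fewer")
  # binned and unbinned fits agree within their standard errors
  pre <- cohort_preset("actin", "csk")
  d <- do.call(synthesize_cohort, cohort_args(pre, n = 100, seed = 2))
  f_cells <- fit_stiffness_model(d)
  f_bins <- fit_stiffness_model(bin_cells(d, 10))
  expect_lt(abs(f_cells$alpha_kpa - f_bins$alpha_kpa),
            2 * (f_cells$se_alpha + f_bins$se_alpha))
})

test_that("the linear stiffness fit is exact on noiseless points and
           recovers simulated parameters", {
  exact <- data.frame(fraction = seq(0.02, 0.3, length.out = 8))
  exact$E_kpa <- 0.4 + 10 * exact$fraction
  f <- fit_stiffness_model(exact)
  expect_equal(f$e0_kpa, 0.4, tolerance = 1e-9)
  expect_equal(f$alpha_kpa, 10, tolerance = 1e-9)
  expect_equal(f$r2, 1)
  expect_error(fit_stiffness_model(
    data.frame(fraction = rep(0.1, 5), E_kpa = 1:5)), "degenerate")
  pre <- cohort_preset("actin", "csk")
  d <- do.call(synthesize_cohort, cohort_args(pre, n = 80, seed = 5))
  fd <- fit_stiffness_model(d)
  expect_lt(abs(fd$e0_kpa - 0.37), 2.6 * fd$se_e0)
  expect_lt(abs(fd$alpha_kpa - 9.48), 2.6 * fd$se_alpha)
})

test_that("for one predictor the slope t-test equals the model F-test", {
  set.seed(3)
  d <- data.frame(fraction = runif(40, 0, 0.3))
  d$E_kpa <- 0.5 + 8 * d$fraction + rnorm(40, 0, 0.6)
  f <- fit_stiffness_model(d)
  expect_equal(f$p_alpha, f$p_vs_constant, tolerance = 1e-10)
})

test_that("the covariance analysis is symmetric and null on duplicated
           cohorts", {
  pre <- cohort_preset("actin", "csk")
  d <- do.call(synthesize_cohort, cohort_args(pre, n = 60, seed = 8))
  same <- compare_fits_ancova(d, d)
  expect_gt(same$p_slope, 0.99)
  pm <- cohort_preset("myosin", "csk")
  d2 <- do.call(synthesize_cohort, cohort_args(pm, n = 60, seed = 9))
  ab <- compare_fits_ancova(d, d2)
  ba <- compare_fits_ancova(d2, d)
  expect_equal(ab$p_slope, ba$p_slope, tolerance = 1e-12)
  expect_equal(ab$p_intercept, ba$p_intercept, tolerance = 1e-12)
})

test_that("model selection keeps the constant model when architecture
           has no effect", {
  pre <- cohort_preset("actin", "csk")
  d <- do.call(synthesize_cohort, cohort_args(
    pre, n = 80, seed = 12,
    modulation = list(a = 1, b = 0, c = 0, d = 0, sigma_ratio = 0.05)))
  f <- fit_stiffness_model(d)
  m <- fit_modulation_model(d, f)
  expect_identical(m$terms, character(0))
})

test_that("model selection recovers clear alignment/location and
           thickness effects with the right signs", {
  actin_like <- synthesize_cohort(
    100, 0.37, 9.48, f_median = 0.059,
    modulation = list(a = 1.10, b = -0.39, c = 0, d = 0.45,
                      sigma_ratio = 0.08),
    arch = cohort_preset("actin")$arch, seed = 31)
  fa <- fit_stiffness_model(actin_like)
  ma <- fit_modulation_model(actin_like, fa)
  expect_setequal(ma$terms, c("fa", "rl"))
  expect_lt(ma$coefficients["fa", 1], 0)
  expect_gt(ma$coefficients["rl", 1], 0)
  myosin_like <- synthesize_cohort(
    100, 0.50, 14.67, f_median = 0.034,
    modulation = list(a = 0.93, b = 0, c = 0.23, d = 0,
                      sigma_ratio = 0.08),
    arch = cohort_preset("myosin")$arch, seed = 32)
  fm <- fit_stiffness_model(myosin_like)
  mm <- fit_modulation_model(myosin_like, fm)
  expect_identical(mm$terms, "ft")
  expect_gt(mm$coefficients["ft", 1], 0)
})

test_that("the normalized response averages to the intercept-plus-terms
           at mean regressors", {
  d <- synthesize_cohort(200, 0.37, 9.48,
                         modulation = list(a = 1.05, b = -0.2, c = 0,
                                           d = 0.15, sigma_ratio = 0.05),
                         seed = 40)
  f <- fit_stiffness_model(d)
  m <- fit_modulation_model(d, f, term_set = c("fa", "rl"))
  cf <- m$coefficients[, 1]
  expect_equal(unname(sum(cf)),
               mean(d$E_kpa / (f$e0_kpa + f$alpha_kpa * d$fraction)),
               tolerance = 0.02)
})

test_that("derived quantities follow from the fitted lines", {
  dq <- derived_quantities(c(0.37, 9.48), c(0.50, 14.67), c(1.14, 6.52))
  expect_equal(dq$m_vs_a_slope, 9.48 / 14.67, tolerance = 1e-12)
  expect_equal(dq$critical_a_pct, 100 * (1.14 - 0.37) / (9.48 - 6.52),
               tolerance = 1e-12)
  expect_warning(
    same <- derived_quantities(c(0.4, 8), c(0.5, 10), c(1.0, 8)),
    "critical")
  expect_true(is.na(same$critical_a_pct))
})

test_that("a tubulin-like cohort shows no significant stiffness slope", {
  pre <- cohort_preset("tubulin", "csk")
  d <- do.call(synthesize_cohort, cohort_args(pre, n = 60, seed = 14))
  f <- fit_stiffness_model(d)
  expect_gt(f$p_alpha, 0.05)
})
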