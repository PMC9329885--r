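test_that("fit_linear recovers exact and constant responses, rejects degenerate designs", {
  d <- rep(c(0, 10, 100, 1000), each = 3)
  y <- 0.05 - 1e-5 * d
  f <- fit_linear(d, y)
  expect_equal(f$a, 0.05, tolerance = 1e-12)
  expect_equal(f$b, -1e-5, tolerance = 1e-12)
  expect_equal(f$R0, 0.05)
  expect_equal(f$dose_range, c(0, 1000))

  fc <- fit_linear(d, rep(0.42, length(d)))
  expect_equal(fc$b, 0)
  expect_equal(fc$a, 0.42)

  expect_error(fit_linear(rep(5, 6), rnorm(6)), "degenerate")
  expect_error(fit_linear(c(0, 1, 2), c(1, Inf, 2)), "finite")
})

test_that("fit_linear matches the closed-form OLS oracle on noisy data", {
  des <- recovery_design()
  tab <- generate_study(des, recovery_truth(a = 0.04563), seed = 11)
  dat <- pooled_doses(tab, des)
  f <- fit_linear(dat$doses, dat$responses)
  o <- ols_oracle(dat$doses, dat$responses)
  expect_equal(f$a, o$a, tolerance = 1e-10)
  expect_equal(f$b, o$b, tolerance = 1e-10)
  # estimates sit inside the oracle 95% CI around the truth for this seed
  expect_lt(abs(f$b - (-6.45e-6)), qt(0.975, o$n - 2) * o$se_b)
  expect_lt(abs(f$a - 0.04563), qt(0.975, o$n - 2) * o$se_a)
})

test_that("candidate models on linear data agree; sharp low-dose drop favours Hill", {
  set.seed(42)
  d <- rep(c(0, 1, 10, 100, 1000, 2000), each = 20)
  y_lin <- 0.06 - 1e-5 * d + rnorm(length(d), sd = 0.005)
  fits <- fit_candidates(d, y_lin)
  aic <- sapply(fits, `[[`, "AIC")
  names(aic) <- sapply(fits, `[[`, "model")
  expect_true(all(sapply(fits, `[[`, "converged")))
  expect_lt(max(aic[c("linear", "power", "polynomial2")]) -
              min(aic[c("linear", "power", "polynomial2")]), 2)

  # step response: control high, everything dosed low
  y_hill <- ifelse(d == 0, 0.064, 0.046) + rnorm(length(d), sd = 0.004)
  fits2 <- fit_candidates(d, y_hill)
  aic2 <- stats::setNames(sapply(fits2, `[[`, "AIC"), sapply(fits2, `[[`, "model"))
  expect_lt(aic2[["hill"]], aic2[["linear"]])

  one <- fit_candidates(d, y_lin, models = "linear")
  expect_length(one, 1)
  expect_identical(one[[1]]$model, "linear")
})

test_that("Hill/exponential demand four dose levels and report failure rather than vanish", {
  set.seed(1)
  d <- rep(c(0, 10, 100), each = 10)
  y <- 0.06 - 1e-5 * d + rnorm(length(d), sd = 0.004)
  fits <- fit_candidates(d, y, models = c("linear", "hill", "exponential3"))
  status <- stats::setNames(sapply(fits, `[[`, "status"), sapply(fits, `[[`, "model"))
  expect_identical(unname(status["hill"]), "insufficient_dose_levels")
  expect_identical(unname(status["exponential3"]), "insufficient_dose_levels")
  expect_identical(unname(status["linear"]), "ok")
})

test_that("AIC ranking is invariant to dose-unit rescaling", {
  set.seed(5)
  d <- rep(c(0, 0.76, 3.2, 50, 2066), each = 12)
  y <- 0.0637 - 6.45e-6 * d + rnorm(length(d), sd = 0.01)
  f_ugl <- fit_candidates(d, y)
  f_um <- fit_candidates(d / 500.13, y)  # ug/L -> uM
  aic1 <- stats::setNames(sapply(f_ugl, `[[`, "AIC"), sapply(f_ugl, `[[`, "model"))
  aic2 <- stats::setNames(sapply(f_um, `[[`, "AIC"), sapply(f_um, `[[`, "model"))
  expect_equal(aic1[names(aic2)], aic2, tolerance = 1e-6)
})

test_that("linear BMD equals the closed form and carries the extrapolation flag", {
  # |b| = 1e-3 per ug/L, control SD 0.01, BMR 1 SD -> BMD = 10 ug/L
  set.seed(2)
  d <- rep(c(0, 5, 10, 20, 40), each = 30)
  y <- 0.5 - 1e-3 * d + rnorm(length(d), sd = 1e-4)
  f <- fit_linear(d, y)
  res <- compute_bmd(f, control_mean = f$R0, control_sd = 0.01, bmr_sd = 1)
  expect_equal(res$bmd, 0.01 / abs(f$b), tolerance = 1e-9)
  expect_lte(res$bmdl, res$bmd)
  expect_gt(res$bmdl, 0)
  # BMD 10 with lowest nonzero dose 5 -> no extrapolation concern
  expect_identical(res$qc_flag, "ok")

  # huge control SD pushes the BMR beyond the curve within 10x the range
  res2 <- compute_bmd(f, f$R0, control_sd = 10, bmr_sd = 1)
  expect_identical(res2$status, "no_solution")

  # a steep BMR far below the lowest tested dose trips the 3x rule
  res3 <- compute_bmd(f, f$R0, control_sd = 1e-3, bmr_sd = 1)
  expect_equal(res3$bmd, 1e-3 / abs(f$b), tolerance = 1e-9)
  expect_identical(res3$qc_flag, "questionable_extrapolation")
})

test_that("profile BMDL tightens to the BMD as residual noise vanishes", {
  d <- rep(c(0, 10, 100, 500, 1000), each = 20)
  set.seed(3)
  gaps <- numeric(2)
  for (i in 1:2) {
    sdv <- c(0.01, 1e-4)[i]
    y <- 0.5 - 2e-4 * d + rnorm(length(d), sd = sdv)
    f <- fit_linear(d, y)
    res <- compute_bmd(f, f$R0, control_sd = 0.05, bmr_sd = 1)
    expect_lt(res$bmdl, res$bmd)  # strict when residual variance > 0
    gaps[i] <- (res$bmd - res$bmdl) / res$bmd
  }
  expect_lt(gaps[2], gaps[1] / 10)
})

test_that("nonlinear BMDs solve the benchmark equation and profile below the BMD", {
  set.seed(9)
  d <- rep(c(0, 50, 200, 800, 2000), each = 25)
  y <- 0.06 * exp(-4e-4 * d) + rnorm(length(d), sd = 0.004)
  fits <- fit_candidates(d, y, models = c("exponential3", "hill", "power"))
  ctrl_sd <- sd(y[d == 0])
  for (f in Filter(function(x) x$converged, fits)) {
    res <- compute_bmd(f, mean(y[d == 0]), ctrl_sd, bmr_sd = 1)
    if (res$status != "ok") next
    # the BMD solves m(0) - m(BMD) = delta
    expect_equal(f$mean_fun(0) - f$mean_fun(res$bmd), ctrl_sd,
                 tolerance = 1e-6 * ctrl_sd)
    expect_lte(res$bmdl, res$bmd)
    expect_gt(res$bmdl, 0)
  }
})

test_that("non-monotonic top group is excluded exactly when the reversal exceeds 1 SD", {
  means <- c(0.064, 0.063, 0.063, 0.062, 0.046, 0.075)
  kept <- suppressMessages(exclude_nonmonotonic_top(means, 0.013))
  expect_equal(as.integer(kept), 1:5)
  expect_true(attr(kept, "dropped_top"))

  kept2 <- suppressMessages(
    exclude_nonmonotonic_top(c(0.064, 0.060, 0.055, 0.048, 0.040, 0.030), 0.013))
  expect_equal(as.integer(kept2), 1:6)
  expect_false(attr(kept2, "dropped_top"))

  # reversal smaller than one control SD is tolerated
  kept3 <- suppressMessages(
    exclude_nonmonotonic_top(c(0.064, 0.060, 0.050, 0.040, 0.030, 0.035), 0.013))
  expect_false(attr(kept3, "dropped_top"))

  expect_error(exclude_nonmonotonic_top(c(1, 2), 0.1), "at least 3")
})
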