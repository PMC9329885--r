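fits <- sba_reference_fits()

test_that("the five-step balance reproduces the published mixture table", {
  tab <- equivalent_dose_balance(fits$pfos_component, fits$pfos_mixture,
                                 fits$fts_mixture)
  row <- function(lev) tab[abs(tab$level - lev) < 1e-9, ]
  expect_identical(row(0.2)$flag, "below_intercept")
  expect_identical(row(0.3)$flag, "antagonistic")
  expect_identical(row(0.4)$flag, "antagonistic")
  expect_true(is.na(row(0.3)$rp_co_index))
  expect_equal(row(0.5)$balance, 495, tolerance = 0.02)
  expect_equal(row(0.5)$rp_co_index, 37.8, tolerance = 0.02)
  expect_equal(row(0.9)$rp_co_index, 11.0, tolerance = 0.02)
  expect_equal(row(0.8)$rp_index_co, 0.081, tolerance = 0.02)
})

test_that("balance decomposition is exact and degenerate mixtures balance to zero", {
  tab <- equivalent_dose_balance(fits$pfos_component, fits$pfos_mixture,
                                 fits$fts_mixture, grid = seq(0.5, 0.9, 0.1))
  expect_equal(tab$dose_index_mix + tab$balance, tab$dose_index_alone,
               tolerance = 1e-12)
  expect_equal(tab$rp_index_co * tab$rp_co_index, rep(1, nrow(tab)),
               tolerance = 1e-12)
  # mixture fit identical to the component fit: all balances zero, rp zero
  same <- equivalent_dose_balance(fits$pfos_component, fits$pfos_component,
                                  fits$fts_mixture, grid = seq(0.5, 0.9, 0.1))
  expect_equal(same$balance, rep(0, nrow(same)), tolerance = 1e-12)
  # zero balance is not a positive potency: flagged, not ratioed
  expect_true(all(same$flag == "antagonistic"))
})

test_that("mixture relative potencies stay within the reported 10-40 fold band", {
  tab <- equivalent_dose_balance(fits$pfos_component, fits$pfos_mixture,
                                 fits$fts_mixture, grid = seq(0.5, 0.9, 0.1))
  expect_true(all(tab$rp_co_index >= 10 & tab$rp_co_index <= 40))
})

test_that("isoboles join the single-chemical iso-effective doses", {
  iso <- isobole(fits$pfos_component, fits$fts_component, 0.5)
  expect_identical(iso$status, "ok")
  expect_equal(iso$x_intercept, 2136, tolerance = 0.01)
  expect_equal(iso$y_intercept, 45193, tolerance = 0.01)
  # endpoints coincide exactly with the rp_curve doses at the same level
  rp <- rp_curve(fits$pfos_component, fits$fts_component, grid = 0.5)
  expect_identical(iso$x_intercept, rp$dose_index)
  expect_identical(iso$y_intercept, rp$dose_co)

  sym <- isobole(fits$pfos_component, fits$pfos_component, 0.5)
  expect_equal(sym$x_intercept, sym$y_intercept)

  shallow <- isobole(fits$pfos_component, fits$fts_component, 0.10)
  expect_identical(shallow$status, "no_isobole")
  expect_true(is.na(shallow$x_intercept))
})

test_that("interaction calls follow the sign of the deviation from response addition", {
  pf <- fits$pfos_component; ft <- fits$fts_component
  # a point constructed on the additive prediction is called additive
  d <- c(500, 5000)
  pred <- min(max(percent_response(pf, d[1]), 0) +
                max(percent_response(ft, d[2]), 0), 1)
  on_line <- classify_point(c(d, pred), pf, ft)
  expect_identical(on_line$call, "additive")
  expect_equal(on_line$deviation, 0, tolerance = 1e-12)

  # shrinking both doses while holding the observed response flips to synergism
  shrunk <- classify_point(c(0.2 * d, pred), pf, ft, tolerance = 0.04)
  expect_identical(shrunk$call, "synergistic")
  expect_gt(shrunk$deviation, 0)

  # observed far short of the prediction reads as antagonism
  weak <- classify_point(c(d, pred - 0.2), pf, ft)
  expect_identical(weak$call, "antagonistic")

  # the observed top mixture group sits below the additive prediction
  # computed on the control-mean baseline (prediction ~66% vs observed 51%)
  t5 <- classify_point(c(1570, 15229, 0.51), pf, ft)
  expect_equal(t5$predicted, 0.660, tolerance = 0.005)
  expect_identical(t5$call, "antagonistic")

  zero <- classify_point(c(0, 0, 0), linear_dr_fit(0.06, -1e-5, 0.06),
                         linear_dr_fit(0.05, -1e-6, 0.05))
  expect_identical(zero$call, "additive")
  expect_equal(zero$deviation, 0)
})

test_that("response-additivity table flags overprediction across the regimen", {
  des <- default_pfos_fts_designs()$mixture
  regimen <- tibble::tibble(treatment = des$groups$label,
                            conc_index = des$groups$PFOS,
                            conc_co = des$groups$FTS62)
  # observed responses: near-zero until the top group, ~51% at T5
  observed <- c(0, 0.02, 0.03, 0.05, 0.08, 0.51)
  tab <- response_additivity_table(fits$pfos_component, fits$fts_component,
                                   regimen, observed)
  # independent arithmetic oracle for the predicted sums
  oracle <- pmin(
    (1 - (0.04563 - 6.45e-6 * regimen$conc_index) / 0.0637) +
      (1 - (0.05499 - 5.60e-7 * regimen$conc_co) / 0.0594), 1)
  expect_equal(tab$pred_sum, oracle, tolerance = 1e-9)
  # additivity overpredicts every group here (T1-T4 pattern and beyond)
  expect_true(all(tab$overpredicted[2:5]))
  # at zero dose the prediction is each fit's baseline response
  expect_equal(tab$pred_index[1], percent_response(fits$pfos_component, 0))
  expect_equal(tab$pred_co[1], percent_response(fits$fts_component, 0))

  bad <- regimen; bad$conc_co[2] <- NA
  expect_error(response_additivity_table(fits$pfos_component, fits$fts_component,
                                         bad, observed), "both analyte")
})
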