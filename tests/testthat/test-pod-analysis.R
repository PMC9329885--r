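make_rep_means <- function(values_by_group) {
  tibble::tibble(
    treatment = rep(names(values_by_group), lengths(values_by_group)),
    replicate = unlist(lapply(values_by_group, seq_along)),
    value = unlist(values_by_group)
  )
}

test_that("replicate means aggregate surviving fish and rates over all embryos", {
  tab <- tibble::tibble(
    experiment = "E", replicate = rep(1:3, each = 20),
    treatment = "T1",
    alive = rep(c(rep(TRUE, 15), rep(FALSE, 5)), 3),
    hatched = TRUE,
    SBA_mm2 = ifelse(rep(c(rep(TRUE, 15), rep(FALSE, 5)), 3), 0.05, NA),
    BL_mm = 3.7, YSA_mm2 = 0.25
  )
  rm_sba <- replicate_means(tab, "SBA_mm2")
  expect_equal(rm_sba$value, rep(0.05, 3))
  rm_mort <- replicate_means(tab, "mortality")
  expect_equal(rm_mort$value, rep(5 / 20, 3))

  # brute-force oracle on generated data
  des <- default_pfos_fts_designs()$pfos
  gtab <- generate_study(des, default_truth_model(), seed = 13)
  got <- replicate_means(gtab, "SBA_mm2")
  for (i in seq_len(nrow(got))) {
    sub <- gtab[gtab$treatment == got$treatment[i] &
                  gtab$replicate == got$replicate[i] & gtab$alive, ]
    expect_equal(got$value[i], mean(sub$SBA_mm2))
  }
})

test_that("pairwise ANOVA separates an extreme shift and ignores identical groups", {
  set.seed(1)
  shifted <- make_rep_means(list(
    Control = 0.06 + rnorm(3, sd = 0.001),
    T1 = 0.06 + rnorm(3, sd = 0.001),
    T2 = 0.06 - 0.01 + rnorm(3, sd = 0.001)  # 10 within-group SDs
  ))
  pw <- anova_pairwise(shifted)
  expect_false(pw$significant[pw$treatment == "T1"])
  expect_true(pw$significant[pw$treatment == "T2"])
  expect_lt(pw$diff[pw$treatment == "T2"], 0)

  flat <- make_rep_means(list(Control = 1 + rnorm(3, sd = 1e-8),
                              T1 = 1 + rnorm(3, sd = 1e-8)))
  pw2 <- anova_pairwise(flat)
  expect_false(pw2$significant[1])

  allconst <- make_rep_means(list(Control = rep(1, 3), T1 = rep(1, 3)))
  expect_warning(anova_pairwise(allconst), "zero within-group variance")
})

test_that("NOAEL/LOAEL derivation covers bounded and both unbounded patterns", {
  doses <- c(T1 = 0.76, T2 = 3.2, T3 = 50, T4 = 2066, T5 = 7475)
  as_pw <- function(sig) {
    structure(tibble::tibble(treatment = names(doses), diff = -0.01,
                             p_adj = ifelse(sig, 0.01, 0.5), significant = sig),
              alpha = 0.05, control = "Control",
              class = c("pairwise_result", "tbl_df", "tbl", "data.frame"))
  }
  # significant at the lowest dose only -> unbounded-low LOAEL, no NOAEL
  ps <- suppressWarnings(
    derive_noael_loael(as_pw(c(TRUE, FALSE, FALSE, FALSE, FALSE)), doses))
  expect_null(ps$noael)
  expect_equal(ps$loael$value, 0.76)
  expect_identical(ps$loael$qualifier, "unbounded_low")

  # nothing significant -> NOAEL at the top dose, unbounded high
  ps2 <- derive_noael_loael(as_pw(rep(FALSE, 5)), doses)
  expect_null(ps2$loael)
  expect_equal(ps2$noael$value, 7475)
  expect_identical(ps2$noael$qualifier, "unbounded_high")

  # significant from T4 up -> bounded NOAEL at T3, bounded LOAEL at T4
  ps3 <- derive_noael_loael(as_pw(c(FALSE, FALSE, FALSE, TRUE, TRUE)), doses)
  expect_equal(ps3$noael$value, 50)
  expect_equal(ps3$loael$value, 2066)
  expect_identical(ps3$noael$qualifier, "bounded")
  expect_lt(ps3$noael$value, ps3$loael$value)

  # significant at T4 but not T5: LOAEL at T4 with a non-monotonicity warning
  expect_warning(
    ps4 <- derive_noael_loael(as_pw(c(FALSE, FALSE, FALSE, TRUE, FALSE)), doses),
    "non-monotonic")
  expect_equal(ps4$loael$value, 2066)
})

test_that("LOAEL never rises when a response gets stronger (monotone consistency)", {
  doses <- c(T1 = 1, T2 = 10, T3 = 100)
  base_sig <- c(FALSE, FALSE, TRUE)
  stronger <- c(FALSE, TRUE, TRUE)  # T2 becomes significant as well
  as_pw <- function(sig) {
    structure(tibble::tibble(treatment = names(doses), diff = -1,
                             p_adj = ifelse(sig, 0.01, 0.5), significant = sig),
              alpha = 0.05, control = "C",
              class = c("pairwise_result", "tbl_df", "tbl", "data.frame"))
  }
  l1 <- derive_noael_loael(as_pw(base_sig), doses)$loael$value
  l2 <- derive_noael_loael(as_pw(stronger), doses)$loael$value
  expect_lte(l2, l1)
})

test_that("POD ratios propagate inequality qualifiers and stay reciprocal", {
  # unbounded-low numerator over unbounded-high denominator: an upper bound
  r <- pod_ratio(pod(0.76, "unbounded_low"), pod(15530, "unbounded_high"))
  expect_equal(r$ratio, 0.76 / 15530)
  expect_equal(signif(r$ratio, 2), 4.9e-5)
  expect_identical(r$qualifier, "upper_bound")
  expect_identical(unname(format_qualifier(r$qualifier)), "<")

  # the inverse reads as a lower bound
  r2 <- pod_ratio(pod(15530, "unbounded_high"), pod(0.76, "unbounded_low"))
  expect_equal(signif(r2$ratio, 3), 20400)
  expect_identical(r2$qualifier, "lower_bound")

  r3 <- pod_ratio(pod(100), pod(100))
  expect_identical(r3$qualifier, "exact")
  expect_equal(r3$ratio, 1)

  # reciprocity for bounded inputs
  a <- pod(1739); b <- pod(14260)
  expect_equal(pod_ratio(a, b)$ratio * pod_ratio(b, a)$ratio, 1, tolerance = 1e-12)

  # qualifier algebra is closed over all nine combinations
  quals <- c("bounded", "unbounded_low", "unbounded_high")
  for (qn in quals) for (qd in quals) {
    out <- pod_ratio(pod(2, qn), pod(4, qd))
    expect_true(out$qualifier %in%
                  c("exact", "upper_bound", "lower_bound", "indeterminate"))
  }
  expect_identical(pod_ratio(pod(2, "unbounded_low"), pod(4, "unbounded_low"))$qualifier,
                   "indeterminate")
  expect_error(pod(-1), "value > 0")
})
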