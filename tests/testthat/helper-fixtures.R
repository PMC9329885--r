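# Shared fixtures and independent oracles used across test files.

# A low-dose study design (component dose range with the top group dropped,
# as done before curve fitting) where zero-truncation of the Gaussian noise
# is negligible, so OLS theory applies cleanly.
recovery_design <- function(n_embryos = 20) {
  study_design(
    analytes = "PFOS",
    groups = tibble::tibble(label = c("Control", paste0("T", 1:4)),
                            PFOS = c(0, 0.76, 3.2, 50, 2066)),
    n_replicates = 3,
    n_embryos_per_replicate = n_embryos,
    endpoints = "SBA_mm2"
  )
}

recovery_truth <- function(a = 0.0637, b = -6.45e-6, sd = 0.013,
                           mortality = 0, hatch = 0.9) {
  truth_model(endpoints = list(SBA_mm2 = list(a = a, b = b, sd = sd)),
              weights = c(PFOS = 1), mortality = mortality, hatch = hatch)
}

# doses/responses vectors from a generated table, alive fish only
pooled_doses <- function(tab, design, endpoint = "SBA_mm2") {
  dmap <- stats::setNames(design$groups[[design$analytes[1]]],
                          design$groups$label)
  alive <- tab[tab$alive & !is.na(tab[[endpoint]]), ]
  list(doses = unname(dmap[alive$treatment]), responses = alive[[endpoint]])
}

# Independent OLS oracle: closed-form slope/intercept and standard errors.
ols_oracle <- function(x, y) {
  n <- length(x)
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  resid <- y - a - b * x
  s2 <- sum(resid^2) / (n - 2)
  se_b <- sqrt(s2 / sum((x - mean(x))^2))
  se_a <- sqrt(s2 * (1 / n + mean(x)^2 / sum((x - mean(x))^2)))
  list(a = a, b = b, se_a = se_a, se_b = se_b, n = n)
}

# Independent bisection inversion of percent_response, used as an oracle
# against the closed-form dose_at_response.
bisect_dose <- function(fit, level, hi = 1e8, tol = 1e-12) {
  f <- function(d) percent_response(fit, d) - level
  lo <- 0
  if (f(lo) > 0 || f(hi) < 0) return(NA_real_)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
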