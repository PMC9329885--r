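#' Linear dose-response fit
#'
#' Container for the linear dose-response model \eqn{R_i = a + b D_i}, the
#' workhorse model for continuous morphometric endpoints (swim bladder area,
#' body length, yolk sac area). The percent-response machinery
#' ([percent_response()], [dose_at_response()]) measures change against the
#' *observed control-group mean* `R0`, which is generally not equal to the
#' fitted intercept `a`.
#'
#' @param a Intercept, in endpoint units (e.g. mm^2).
#' @param b Slope, in endpoint units per ug/L. Negative for endpoints that
#'   decrease with dose.
#' @param R0 Control-group mean response, in endpoint units. Must be > 0.
#' @param control_sd Control-group standard deviation (endpoint units), or
#'   `NA` when unknown (e.g. a fit built from published parameters).
#' @param n Number of observations behind the fit, or `NA`.
#' @param residual_sd Residual standard deviation of the fit, or `NA`.
#' @param dose_range Length-2 numeric, the dose range (ug/L) used in fitting.
#' @param data Optional list with elements `doses` and `responses`, retained
#'   so that likelihood-based intervals can be profiled later.
#'
#' @return An object of class `linear_dr_fit`.
#' @examples
#' # Published PFOS component fit for swim bladder area
#' f <- linear_dr_fit(a = 0.04563, b = -6.45e-6, R0 = 0.0637)
#' dose_at_response(f, 0.5)
#' @export
linear_dr_fit <- function(a, b, R0, control_sd = NA_real_, n = NA_integer_,
                          residual_sd = NA_real_, dose_range = c(NA_real_, NA_real_),
                          data = NULL) {
  stopifnot(is.numeric(a), length(a) == 1, is.finite(a),
            is.numeric(b), length(b) == 1, is.finite(b),
            is.numeric(R0), length(R0) == 1)
  if (!is.na(R0) && R0 <= 0) {
    stop("control mean `R0` must be positive for area/length endpoints", call. = FALSE)
  }
  if (!is.na(control_sd) && control_sd <= 0) {
    stop("`control_sd` must be positive", call. = FALSE)
  }
  if (!anyNA(dose_range) && dose_range[1] < 0) {
    stop("`dose_range` minimum must be >= 0", call. = FALSE)
  }
  structure(
    list(a = a, b = b, R0 = R0, control_sd = control_sd,
         n = as.integer(n), residual_sd = residual_sd,
         dose_range = as.numeric(dose_range), data = data),
    class = "linear_dr_fit"
  )
}

#' @export
print.linear_dr_fit <- function(x, ...) {
  cat("Linear dose-response fit: R(D) = a + b * D\n")
  cat(sprintf("  a (intercept)    : %.5g\n", x$a))
  cat(sprintf("  b (slope)        : %.5g per ug/L\n", x$b))
  cat(sprintf("  R0 (control mean): %.5g\n", x$R0))
  if (!is.na(x$control_sd)) cat(sprintf("  control SD       : %.5g\n", x$control_sd))
  if (!is.na(x$n)) cat(sprintf("  n                : %d\n", x$n))
  if (!anyNA(x$dose_range)) {
    cat(sprintf("  dose range       : [%.4g, %.4g] ug/L\n",
                x$dose_range[1], x$dose_range[2]))
  }
  invisible(x)
}

#' Fit the linear dose-response model by ordinary least squares
#'
#' Fits \eqn{R_i = a + b D_i} to individual observations pooled across
#' replicates. Under constant-variance Gaussian errors the OLS estimates are
#' the maximum-likelihood estimates. The control mean `R0` and control SD are
#' computed from the dose-0 records only, matching the percent-response
#' convention where change is measured against the observed control mean.
#'
#' @param doses Numeric vector of doses (ug/L), >= 0.
#' @param responses Numeric vector of responses (endpoint units), finite,
#'   same length as `doses`.
#'
#' @return A [linear_dr_fit] with the raw data attached (for profiling).
#' @examples
#' d <- rep(c(0, 10, 100, 1000), each = 5)
#' r <- 0.05 - 1e-5 * d + rnorm(length(d), sd = 1e-3)
#' fit_linear(d, r)
#' @export
fit_linear <- function(doses, responses) {
  stopifnot(is.numeric(doses), is.numeric(responses),
            length(doses) == length(responses))
  keep <- !is.na(responses) & !is.na(doses)
  doses <- doses[keep]; responses <- responses[keep]
  if (length(doses) < 3) stop("need at least 3 observations", call. = FALSE)
  if (any(!is.finite(responses))) stop("responses must be finite", call. = FALSE)
  if (any(doses < 0)) stop("doses must be non-negative", call. = FALSE)
  if (length(unique(doses)) < 2) {
    stop("degenerate design: all doses identical; need >= 2 distinct dose levels",
         call. = FALSE)
  }
  fit <- stats::lm(responses ~ doses)
  cf <- stats::coef(fit)
  ctrl <- responses[doses == 0]
  R0 <- if (length(ctrl) >= 1) mean(ctrl) else NA_real_
  csd <- if (length(ctrl) >= 2) stats::sd(ctrl) else NA_real_
  if (!is.na(csd) && csd == 0) csd <- NA_real_  # degenerate (noise-free) controls
  linear_dr_fit(
    a = unname(cf[1]), b = unname(cf[2]),
    R0 = R0, control_sd = csd,
    n = length(doses),
    residual_sd = sqrt(sum(stats::resid(fit)^2) / stats::df.residual(fit)),
    dose_range = range(doses),
    data = list(doses = doses, responses = responses)
  )
}
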