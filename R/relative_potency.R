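#' Percent response relative to the control mean
#'
#' Converts a predicted endpoint value into a fractional response, defined as
#' the fractional reduction from the observed control-group mean:
#' \deqn{\%\,response = (R_0 - R_i)/R_0,\qquad R_i = a + b D_i.}
#' A negative value means the model predicts a response *above* the control
#' mean at that dose. Because the fitted intercept `a` typically sits below
#' `R0`, the percent response at dose 0 is usually positive (for the PFOS
#' component fit it is about 28%).
#'
#' @param fit A [linear_dr_fit].
#' @param dose Numeric vector of doses (ug/L), >= 0.
#' @return Numeric vector of response fractions (0.5 means a 50% reduction).
#' @examples
#' f <- linear_dr_fit(a = 0.04563, b = -6.45e-6, R0 = 0.0637)
#' percent_response(f, c(0, 2136))
#' @export
percent_response <- function(fit, dose) {
  stopifnot(inherits(fit, "linear_dr_fit"), is.numeric(dose), all(dose >= 0))
  if (is.na(fit$R0) || fit$R0 == 0) {
    stop("control mean `R0` is zero or unknown; percent response undefined",
         call. = FALSE)
  }
  1 - (fit$a + fit$b * dose) / fit$R0
}

#' Dose producing a given percent response (linear-model inversion)
#'
#' Inverts the linear dose-response model at a response level expressed as a
#' fraction of the control mean:
#' \deqn{D_i = \frac{R_0 (1 - \%\,response) - a}{b}.}
#' When the requested level is shallower than what the model already predicts
#' at dose 0 (the intercept sits below the control mean), the inversion gives
#' a non-positive dose; this is reported as status `"below_intercept"` with an
#' `NA` dose rather than a negative number.
#'
#' @param fit A [linear_dr_fit] with `b != 0`.
#' @param level Numeric vector of response fractions in (0, 1).
#' @return A [tibble][tibble::tibble] with columns `level`, `dose` (ug/L, `NA`
#'   when not achievable) and `status` (`"ok"` or `"below_intercept"`).
#' @examples
#' fts <- linear_dr_fit(a = 0.05499, b = -5.60e-7, R0 = 0.0594)
#' dose_at_response(fts, c(0.2, 0.5))
#' @export
dose_at_response <- function(fit, level) {
  stopifnot(inherits(fit, "linear_dr_fit"), is.numeric(level))
  if (any(level <= 0 | level >= 1)) {
    stop("response levels must lie strictly within (0, 1)", call. = FALSE)
  }
  if (fit$b == 0) stop("slope is zero: no dose solves the response level", call. = FALSE)
  d <- (fit$R0 * (1 - level) - fit$a) / fit$b
  status <- ifelse(d > 0, "ok", "below_intercept")
  tibble::tibble(level = level,
                 dose = ifelse(d > 0, d, NA_real_),
                 status = status)
}

#' Relative-potency curve across response levels
#'
#' For an index chemical and a co-chemical, inverts both linear fits across a
#' grid of response levels and tabulates the iso-effective doses and their
#' ratios. The co/index ratio is the dose of co-chemical needed to match the
#' effect of one unit of index chemical, i.e. the reciprocal of its relative
#' potency; its variation across levels is the central argument against a
#' constant relative potency factor.
#'
#' @param fit_index,fit_co [linear_dr_fit] objects for the index chemical
#'   (e.g. PFOS) and the co-chemical (e.g. 6:2 FTS).
#' @param grid Response-level grid, fractions in (0, 1). Default 20% to 90%
#'   in steps of 10%.
#' @return A tibble with columns `level`, `dose_index`, `dose_co`,
#'   `ratio_index_co`, `ratio_co_index`, `status`. Ratios are `NA` unless both
#'   doses are achievable.
#' @examples
#' pfos <- linear_dr_fit(a = 0.04563, b = -6.45e-6, R0 = 0.0637)
#' fts  <- linear_dr_fit(a = 0.05499, b = -5.60e-7, R0 = 0.0594)
#' rp_curve(pfos, fts)
#' @export
rp_curve <- function(fit_index, fit_co, grid = seq(0.2, 0.9, by = 0.1)) {
  di <- dose_at_response(fit_index, grid)
  dc <- dose_at_response(fit_co, grid)
  ok <- di$status == "ok" & dc$status == "ok"
  tibble::tibble(
    level = grid,
    dose_index = di$dose,
    dose_co = dc$dose,
    ratio_index_co = ifelse(ok, di$dose / dc$dose, NA_real_),
    ratio_co_index = ifelse(ok, dc$dose / di$dose, NA_real_),
    status = ifelse(ok, "ok", "below_intercept")
  )
}

#' Limiting relative potency at full response
#'
#' As the response level approaches 100%, the co/index dose ratio from the two
#' linear fits converges to the ratio of the doses at which each fitted line
#' reaches zero response (the x-intercepts):
#' \deqn{\lim_{p \to 1} \frac{D_{co}(p)}{D_{index}(p)}
#'   = \frac{a_{co}/|b_{co}|}{a_{index}/|b_{index}|}.}
#' For the published component fits this is about 13.9, i.e. the co-chemical
#' is roughly 14-fold less potent in the limit.
#'
#' @inheritParams rp_curve
#' @return A single number, the limiting co/index dose ratio.
#' @export
rp_limit <- function(fit_index, fit_co) {
  stopifnot(inherits(fit_index, "linear_dr_fit"), inherits(fit_co, "linear_dr_fit"))
  if (fit_index$b >= 0 || fit_co$b >= 0) {
    stop("rp_limit requires negative slopes for both fits", call. = FALSE)
  }
  (fit_co$a / abs(fit_co$b)) / (fit_index$a / abs(fit_index$b))
}

#' Published swim-bladder-area linear fits for PFOS and 6:2 FTS
#'
#' The linear dose-response parameter sets for the swim bladder area endpoint
#' reported for the PFOS and 6:2 FTS component experiments and for each
#' component measured within the binary-mixture experiment. These are the
#' inputs for reproducing the full-curve relative-potency and dose-balance
#' tables without the raw per-fish data.
#'
#' @return A named list of four [linear_dr_fit] objects:
#'   `pfos_component`, `fts_component`, `pfos_mixture`, `fts_mixture`.
#' @examples
#' fits <- sba_reference_fits()
#' rp_curve(fits$pfos_component, fits$fts_component)
#' @export
sba_reference_fits <- function() {
  list(
    pfos_component = linear_dr_fit(a = 0.04563, b = -6.45e-6, R0 = 0.0637),
    fts_component  = linear_dr_fit(a = 0.05499, b = -5.60e-7, R0 = 0.0594),
    pfos_mixture   = linear_dr_fit(a = 0.05218, b = -1.57e-5, R0 = 0.0529),
    fts_mixture    = linear_dr_fit(a = 0.05250, b = -1.39e-6, R0 = 0.0529)
  )
}
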