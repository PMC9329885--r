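# Index-chemical dose-balance procedure for binary-mixture experiments,
# isobole construction (dose addition), and the response-additivity check.

#' Index-chemical equivalent-dose balance across response levels
#'
#' Implements the five-step balance procedure that extracts a relative
#' potency from a whole-mixture experiment. Per response level:
#' \enumerate{
#'   \item dose of the index chemical alone giving that response (component
#'     fit);
#'   \item dose of the index chemical within the mixture giving that response
#'     (mixture fit for the index component);
#'   \item balance = step 1 - step 2, the index-equivalent dose presumed
#'     attributable to the co-chemical;
#'   \item dose of the co-chemical within the mixture at that response
#'     (mixture fit for the co-component);
#'   \item relative potency = balance / co-chemical dose.
#' }
#' A level the index-alone fit cannot reach is flagged `below_intercept`; a
#' non-positive balance (the mixture needs *more* index chemical than the
#' component study at the same response) is flagged `antagonistic` and its
#' ratios are suppressed.
#'
#' @param fit_index_alone Component-study [linear_dr_fit] for the index
#'   chemical.
#' @param fit_index_mix,fit_co_mix Mixture-study fits for the index and
#'   co-chemical components.
#' @param grid Response levels, fractions in (0, 1). Default 20%-90%.
#' @return A tibble with columns `level`, `dose_index_alone`,
#'   `dose_index_mix`, `balance`, `dose_co_mix`, `rp_index_co`
#'   (balance / co dose), `rp_co_index`, `flag`.
#' @examples
#' f <- sba_reference_fits()
#' equivalent_dose_balance(f$pfos_component, f$pfos_mixture, f$fts_mixture)
#' @export
equivalent_dose_balance <- function(fit_index_alone, fit_index_mix, fit_co_mix,
                                    grid = seq(0.2, 0.9, by = 0.1)) {
  stopifnot(inherits(fit_index_alone, "linear_dr_fit"),
            inherits(fit_index_mix, "linear_dr_fit"),
            inherits(fit_co_mix, "linear_dr_fit"))
  d_alone <- dose_at_response(fit_index_alone, grid)
  d_mix <- dose_at_response(fit_index_mix, grid)
  d_co <- dose_at_response(fit_co_mix, grid)
  balance <- d_alone$dose - d_mix$dose
  defined <- d_alone$status == "ok" & d_mix$status == "ok"
  flag <- dplyr::case_when(
    !defined ~ "below_intercept",
    balance <= 0 ~ "antagonistic",
    TRUE ~ "ok"
  )
  ok <- flag == "ok" & d_co$status == "ok"
  tibble::tibble(
    level = grid,
    dose_index_alone = d_alone$dose,
    dose_index_mix = d_mix$dose,
    balance = ifelse(defined, balance, NA_real_),
    dose_co_mix = d_co$dose,
    rp_index_co = ifelse(ok, balance / d_co$dose, NA_real_),
    rp_co_index = ifelse(ok, d_co$dose / balance, NA_real_),
    flag = flag
  )
}

#' Isobole (dose-addition line) for a binary mixture at one response level
#'
#' Under dose additivity, all component-dose combinations giving one fixed
#' response lie on the straight segment joining the two single-chemical
#' iso-effective doses. The intercepts come from inverting each component fit
#' at the requested level; observed mixture points falling below the line
#' suggest synergism, above it antagonism.
#'
#' @param fit_index_alone,fit_co_alone Component-study fits for the index
#'   chemical (x-axis) and co-chemical (y-axis).
#' @param level Response fraction in (0, 1).
#' @return An object of class `isobole_line` with `level`, `x_intercept`,
#'   `y_intercept`, and `status` (`"ok"` or `"no_isobole"` when either
#'   component cannot reach the level).
#' @export
isobole <- function(fit_index_alone, fit_co_alone, level) {
  stopifnot(length(level) == 1)
  dx <- dose_at_response(fit_index_alone, level)
  dy <- dose_at_response(fit_co_alone, level)
  ok <- dx$status == "ok" && dy$status == "ok"
  structure(list(level = level,
                 x_intercept = if (ok) dx$dose else NA_real_,
                 y_intercept = if (ok) dy$dose else NA_real_,
                 status = if (ok) "ok" else "no_isobole"),
            class = "isobole_line")
}

#' @export
print.isobole_line <- function(x, ...) {
  if (x$status == "ok") {
    cat(sprintf("isobole @ %.0f%% response: x-intercept %.4g, y-intercept %.4g ug/L\n",
                100 * x$level, x$x_intercept, x$y_intercept))
  } else {
    cat(sprintf("isobole @ %.0f%% response: not constructible (%s)\n",
                100 * x$level, x$status))
  }
  invisible(x)
}

#' Classify an observed mixture point against the response-additive prediction
#'
#' The additive prediction at a mixture point is the sum of the component
#' percent responses (response addition), each floored at 0 and the sum
#' capped at 1. The observed response is compared to this prediction: an
#' observed response exceeding it by more than `tolerance` is called
#' synergistic (the point lies below its isobole — less of each chemical
#' than additivity requires for that response), falling short of it
#' antagonistic, and within `tolerance` additive.
#'
#' @param point Numeric vector `c(dose_index, dose_co, observed)` with doses
#'   in ug/L (>= 0) and the observed response as a fraction.
#' @param fit_index_alone,fit_co_alone Component-study fits.
#' @param tolerance Absolute response-fraction band for an "additive" call
#'   (default 0.05).
#' @return An object of class `interaction_call`: `observed`, `predicted`,
#'   `deviation` (observed - predicted), and `call` in
#'   `{additive, synergistic, antagonistic}`.
#' @export
classify_point <- function(point, fit_index_alone, fit_co_alone, tolerance = 0.05) {
  stopifnot(is.numeric(point), length(point) == 3, all(point[1:2] >= 0),
            tolerance >= 0)
  pr_i <- max(percent_response(fit_index_alone, point[1]), 0)
  pr_c <- max(percent_response(fit_co_alone, point[2]), 0)
  predicted <- min(pr_i + pr_c, 1)
  deviation <- point[3] - predicted
  call <- if (abs(deviation) <= tolerance) "additive"
          else if (deviation > 0) "synergistic" else "antagonistic"
  structure(list(dose_index = point[1], dose_co = point[2],
                 observed = point[3], predicted = predicted,
                 deviation = deviation, call = call, tolerance = tolerance),
            class = "interaction_call")
}

#' @export
print.interaction_call <- function(x, ...) {
  cat(sprintf("(%.4g, %.4g) ug/L: observed %.1f%%, additive prediction %.1f%% -> %s\n",
              x$dose_index, x$dose_co, 100 * x$observed, 100 * x$predicted, x$call))
  invisible(x)
}

#' Response-additivity check over a mixture dose regimen
#'
#' For each mixture treatment group, predicts the response each component
#' would cause alone at its measured mixture concentration (component-study
#' fits), sums the predictions (capped at 100%), and compares against the
#' observed mixture response. Groups where the sum exceeds the observation
#' are flagged `overpredicted` - the signature of a less-than-additive
#' (antagonistic) joint response.
#'
#' @param fit_index_alone,fit_co_alone Component-study fits.
#' @param mixture_regimen Data frame with columns `treatment`, `conc_index`,
#'   `conc_co` (measured concentrations, ug/L).
#' @param observed_responses Numeric vector of observed response fractions,
#'   one per regimen row.
#' @return A tibble: `treatment`, `conc_index`, `conc_co`, `pred_index`,
#'   `pred_co`, `pred_sum`, `observed`, `overpredicted`.
#' @export
response_additivity_table <- function(fit_index_alone, fit_co_alone,
                                      mixture_regimen, observed_responses) {
  stopifnot(is.data.frame(mixture_regimen),
            all(c("treatment", "conc_index", "conc_co") %in% names(mixture_regimen)),
            length(observed_responses) == nrow(mixture_regimen))
  if (anyNA(mixture_regimen$conc_index) || anyNA(mixture_regimen$conc_co)) {
    stop("every mixture group needs both analyte concentrations", call. = FALSE)
  }
  pred_i <- percent_response(fit_index_alone, mixture_regimen$conc_index)
  pred_c <- percent_response(fit_co_alone, mixture_regimen$conc_co)
  pred_sum <- pmin(pred_i + pred_c, 1)
  tibble::tibble(
    treatment = mixture_regimen$treatment,
    conc_index = mixture_regimen$conc_index,
    conc_co = mixture_regimen$conc_co,
    pred_index = pred_i,
    pred_co = pred_c,
    pred_sum = pred_sum,
    observed = observed_responses,
    overpredicted = pred_sum > observed_responses
  )
}
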