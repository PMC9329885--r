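# NOAEL/LOAEL derivation from replicate-mean ANOVA with Tukey-adjusted
# pairwise contrasts, plus POD-ratio relative potency with inequality
# (bounded/unbounded) propagation.

.rate_endpoints <- c("mortality", "hatch_rate")

#' Per-replicate endpoint means
#'
#' Aggregates a per-fish measurement table to replicate-level means, the unit
#' of analysis for the group-comparison ANOVA. Continuous morphometrics are
#' averaged over surviving fish within each replicate dish; `"mortality"` and
#' `"hatch_rate"` are computed as per-replicate proportions over all embryos.
#'
#' @param table A measurement table as produced by [generate_study()] or
#'   [read_measurements()].
#' @param endpoint One of the continuous endpoint columns (e.g. `"SBA_mm2"`,
#'   `"BL_mm"`, `"YSA_mm2"`) or `"mortality"` / `"hatch_rate"`.
#' @return A tibble with columns `treatment`, `replicate`, `value`, ordered
#'   as in the input. Replicates with no surviving fish get `NA` (with a
#'   warning) for continuous endpoints.
#' @export
replicate_means <- function(table, endpoint) {
  stopifnot(is.data.frame(table),
            all(c("treatment", "replicate", "alive", "hatched") %in% names(table)))
  if (endpoint %in% .rate_endpoints) {
    out <- table |>
      dplyr::group_by(.data$treatment, .data$replicate) |>
      dplyr::summarise(
        value = if (endpoint == "mortality") mean(!.data$alive) else mean(.data$hatched),
        .groups = "drop")
  } else {
    if (!endpoint %in% names(table)) {
      stop("unknown endpoint: ", endpoint, call. = FALSE)
    }
    out <- table |>
      dplyr::filter(.data$alive) |>
      dplyr::group_by(.data$treatment, .data$replicate) |>
      dplyr::summarise(value = mean(.data[[endpoint]], na.rm = TRUE),
                       .groups = "drop")
    # replicates that lost every fish drop out of the filtered table
    full <- dplyr::distinct(table, .data$treatment, .data$replicate)
    out <- dplyr::left_join(full, out, by = c("treatment", "replicate"))
    if (anyNA(out$value)) {
      warning("replicate(s) with no surviving fish: mean recorded as NA",
              call. = FALSE)
    }
  }
  out$value[is.nan(out$value)] <- NA_real_
  out
}

#' One-way ANOVA with Tukey-adjusted control-vs-treatment contrasts
#'
#' Runs a one-way ANOVA on replicate means and extracts every
#' control-vs-treatment contrast with Tukey family-wise adjusted p-values.
#' Operating on replicate means (typically n = 3 dishes per group) rather
#' than individual fish is deliberately conservative: the dish, not the fish,
#' is the independent experimental unit.
#'
#' @param rep_means A tibble from [replicate_means()]; the first treatment
#'   level (in factor or appearance order) is taken as the control.
#' @param alpha Significance level (default 0.05).
#' @return An object of class `pairwise_result`: a tibble with one row per
#'   treatment group (`treatment`, `diff` = mean - control mean, `p_adj`,
#'   `significant`), plus attributes `alpha` and `control`.
#' @export
anova_pairwise <- function(rep_means, alpha = 0.05) {
  stopifnot(is.data.frame(rep_means),
            all(c("treatment", "value") %in% names(rep_means)),
            alpha > 0, alpha < 1)
  dat <- rep_means[!is.na(rep_means$value), ]
  trt <- if (is.factor(dat$treatment)) droplevels(dat$treatment)
         else factor(dat$treatment, levels = unique(rep_means$treatment))
  if (nlevels(trt) < 2) stop("need >= 2 groups", call. = FALSE)
  counts <- table(trt)
  if (any(counts < 2)) stop("need >= 2 replicates per group", call. = FALSE)
  dat$treatment <- trt
  ssw <- sum(tapply(dat$value, trt, function(v) sum((v - mean(v))^2)))
  degenerate <- ssw == 0
  if (degenerate) {
    warning("zero within-group variance in every group: p-values undefined",
            call. = FALSE)
  }
  fit <- stats::aov(value ~ treatment, data = dat)
  tuk <- stats::TukeyHSD(fit)$treatment
  ctrl <- levels(trt)[1]
  others <- levels(trt)[-1]
  rn <- rownames(tuk)
  rows <- vapply(others, function(g) {
    i <- which(rn == paste0(g, "-", ctrl))
    if (length(i) == 0) i <- which(rn == paste0(ctrl, "-", g))
    i[1]
  }, 1L)
  flip <- !grepl(paste0("-", ctrl, "$"), rn[rows])
  res <- tibble::tibble(
    treatment = others,
    diff = ifelse(flip, -tuk[rows, "diff"], tuk[rows, "diff"]),
    p_adj = if (degenerate) NA_real_ else tuk[rows, "p adj"],
    significant = if (degenerate) NA else tuk[rows, "p adj"] < alpha
  )
  structure(res, alpha = alpha, control = ctrl,
            class = c("pairwise_result", class(res)))
}

#' Derive NOAEL and LOAEL with bounded/unbounded qualifiers
#'
#' The LOAEL is the lowest dose with a statistically significant response;
#' the NOAEL is the highest non-significant dose below it. Two boundary cases
#' carry qualifiers: significance already at the lowest tested dose makes the
#' LOAEL *unbounded low* (the true LOAEL may lie lower, and no NOAEL exists);
#' no significance anywhere makes the NOAEL the top dose, *unbounded high*
#' (no LOAEL exists). A significance pattern that turns off again at higher
#' doses (non-monotonic) is reported with a warning, not an error.
#'
#' @param pairwise A `pairwise_result` from [anova_pairwise()].
#' @param group_doses Named numeric vector: dose (ug/L) per treatment group,
#'   in increasing dose order, names matching `pairwise$treatment`.
#' @param endpoint Optional endpoint label carried into the result.
#' @return An object of class `pod_set`: list with `endpoint`, `noael` and
#'   `loael` (each a [pod()] or `NULL`), and `source_groups`.
#' @export
derive_noael_loael <- function(pairwise, group_doses, endpoint = NA_character_) {
  stopifnot(inherits(pairwise, "pairwise_result"),
            is.numeric(group_doses), !is.null(names(group_doses)))
  if (is.unsorted(group_doses)) {
    stop("`group_doses` must be ordered by increasing dose", call. = FALSE)
  }
  sig <- pairwise$significant[match(names(group_doses), pairwise$treatment)]
  if (anyNA(sig)) stop("group_doses names must match pairwise treatments", call. = FALSE)
  k <- length(sig)
  first_sig <- which(sig)[1]
  if (is.na(first_sig)) {
    noael <- pod(group_doses[k], "unbounded_high", names(group_doses)[k])
    loael <- NULL
  } else if (first_sig == 1) {
    noael <- NULL
    loael <- pod(group_doses[1], "unbounded_low", names(group_doses)[1])
  } else {
    below <- seq_len(first_sig - 1)
    ns_below <- below[!sig[below]]
    noael <- pod(group_doses[max(ns_below)], "bounded", names(group_doses)[max(ns_below)])
    loael <- pod(group_doses[first_sig], "bounded", names(group_doses)[first_sig])
  }
  if (!is.na(first_sig) && any(!sig[seq(first_sig, k)])) {
    warning("non-monotonic significance pattern: significant at ",
            names(group_doses)[first_sig], " but not at every higher dose",
            call. = FALSE)
  }
  structure(list(endpoint = endpoint, noael = noael, loael = loael,
                 source_groups = names(group_doses)),
            class = "pod_set")
}

#' Point of departure with an inequality qualifier
#'
#' @param value Dose (ug/L), > 0.
#' @param qualifier `"bounded"` (the study brackets the value),
#'   `"unbounded_low"` (true value may be lower; printed as `<`), or
#'   `"unbounded_high"` (true value may be higher; printed as `>`).
#' @param group Optional source treatment-group label.
#' @return An object of class `pod`.
#' @export
pod <- function(value, qualifier = c("bounded", "unbounded_low", "unbounded_high"),
                group = NA_character_) {
  qualifier <- match.arg(qualifier)
  stopifnot(is.numeric(value), length(value) == 1, value > 0)
  structure(list(value = unname(value), qualifier = qualifier, group = group),
            class = "pod")
}

#' @export
print.pod <- function(x, ...) {
  pre <- switch(x$qualifier, bounded = "", unbounded_low = "<", unbounded_high = ">")
  cat(sprintf("POD %s%g ug/L (%s)\n", pre, x$value, x$qualifier))
  invisible(x)
}

#' @export
print.pod_set <- function(x, ...) {
  cat("POD set", if (!is.na(x$endpoint)) paste0("[", x$endpoint, "]"), "\n")
  cat("  NOAEL: "); if (is.null(x$noael)) cat("none (LOAEL unbounded low)\n") else print(x$noael)
  cat("  LOAEL: "); if (is.null(x$loael)) cat("none (NOAEL unbounded high)\n") else print(x$loael)
  invisible(x)
}

# inequality direction implied by a POD qualifier: the true value is
# "lt" (below the printed number), "gt" (above it), or exact
.pod_dir <- function(p) {
  switch(p$qualifier, bounded = "exact", unbounded_low = "lt", unbounded_high = "gt")
}

#' Ratio of two points of departure with qualifier propagation
#'
#' Computes `pod_num / pod_den` and propagates inequality qualifiers: an
#' unbounded-low numerator or unbounded-high denominator pushes the true
#' ratio *below* the computed value (`upper_bound`, printed `<`); the
#' opposite directions push it above (`lower_bound`, printed `>`). When both
#' inputs are unbounded the same way the direction cannot be determined
#' (`indeterminate`). Full precision is retained; round only at report time
#' (conventionally 2 significant figures).
#'
#' @param pod_num,pod_den [pod()] objects (values > 0).
#' @return An object of class `rp_estimate`: `ratio`, `qualifier` in
#'   `{exact, upper_bound, lower_bound, indeterminate}`, and the inputs.
#' @examples
#' pod_ratio(pod(0.76, "unbounded_low"), pod(15530, "unbounded_high"))
#' @export
pod_ratio <- function(pod_num, pod_den) {
  stopifnot(inherits(pod_num, "pod"), inherits(pod_den, "pod"))
  num <- .pod_dir(pod_num); den <- .pod_dir(pod_den)
  qual <- if (num == "exact" && den == "exact") "exact"
    else if (num == "lt" && den %in% c("exact", "gt")) "upper_bound"
    else if (num == "gt" && den %in% c("exact", "lt")) "lower_bound"
    else if (num == "exact" && den == "lt") "lower_bound"
    else if (num == "exact" && den == "gt") "upper_bound"
    else "indeterminate"
  structure(list(ratio = pod_num$value / pod_den$value, qualifier = qual,
                 numerator = pod_num, denominator = pod_den),
            class = "rp_estimate")
}

#' @export
print.rp_estimate <- function(x, ...) {
  cat(sprintf("relative potency %s%s (%s)\n", format_qualifier(x$qualifier),
              signif(x$ratio, 2), x$qualifier))
  invisible(x)
}

#' Inequality prefix for a ratio qualifier
#'
#' @param qualifier One of `"exact"`, `"upper_bound"`, `"lower_bound"`,
#'   `"indeterminate"`.
#' @return `""`, `"<"`, `">"`, or `"?"`.
#' @export
format_qualifier <- function(qualifier) {
  vapply(qualifier, function(q) switch(q, exact = "", upper_bound = "<",
                                       lower_bound = ">", indeterminate = "?"),
         "")
}
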