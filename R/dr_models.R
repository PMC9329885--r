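# Candidate dose-response curves for continuous endpoints, fitted by
# constant-variance normal maximum likelihood, plus SD-based benchmark-dose
# computation with profile-likelihood lower bounds.

# Internal: doses are rescaled to [0, 1] before optimisation (u = d / dmax)
# so that power/Hill exponents remain numerically tame; mean functions
# returned to the caller accept natural-scale doses.

.curve_models <- c("linear", "power", "polynomial2", "exponential3", "hill")

.mean_fun_scaled <- function(model, params) {
  switch(model,
    linear = function(u) params[["a"]] + params[["b"]] * u,
    power = function(u) params[["a"]] + params[["b"]] * u^params[["g"]],
    polynomial2 = function(u) params[["a"]] + params[["b1"]] * u + params[["b2"]] * u^2,
    exponential3 = function(u) params[["a"]] * exp(params[["k"]] * u^params[["g"]]),
    hill = function(u) {
      params[["a"]] + params[["v"]] * u^params[["g"]] /
        (params[["kd"]]^params[["g"]] + u^params[["g"]])
    },
    stop("unknown model: ", model, call. = FALSE)
  )
}

.loglik_const_var <- function(sse, n) {
  if (sse <= 0) sse <- .Machine$double.xmin
  -n / 2 * (log(2 * pi * sse / n) + 1)
}

# one SSE minimisation with box constraints and a few starts
.fit_sse <- function(objective, starts, lower, upper) {
  best <- NULL
  for (s in starts) {
    res <- tryCatch(
      stats::optim(s, objective, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500, factr = 1e9)),
      error = function(e) NULL
    )
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  best
}

.fit_one_model <- function(model, u, y) {
  n <- length(y)
  ybar0 <- mean(y[u == 0])
  if (!is.finite(ybar0)) ybar0 <- mean(y)
  span <- mean(y[u == max(u)]) - ybar0
  if (!is.finite(span) || span == 0) span <- stats::sd(y) * sign(stats::cor(u, y) + 1e-12)

  if (model == "linear") {
    fit <- stats::lm(y ~ u)
    params <- c(a = unname(stats::coef(fit)[1]), b = unname(stats::coef(fit)[2]))
    sse <- sum(stats::resid(fit)^2)
    return(list(params = params, sse = sse, converged = TRUE, npar_mean = 2))
  }
  if (model == "polynomial2") {
    fit <- stats::lm(y ~ u + I(u^2))
    cf <- stats::coef(fit)
    params <- c(a = unname(cf[1]), b1 = unname(cf[2]), b2 = unname(cf[3]))
    sse <- sum(stats::resid(fit)^2)
    return(list(params = params, sse = sse, converged = TRUE, npar_mean = 3))
  }

  obj_for <- function(nm) {
    function(p) {
      names(p) <- nm
      mu <- .mean_fun_scaled(model, as.list(p))(u)
      if (any(!is.finite(mu))) return(1e300)
      sum((y - mu)^2)
    }
  }
  if (model == "power") {
    nm <- c("a", "b", "g")
    starts <- lapply(c(1, 2, 4), function(g) c(a = ybar0, b = span, g = g))
    res <- .fit_sse(obj_for(nm), starts,
                    lower = c(-Inf, -Inf, 1), upper = c(Inf, Inf, 18))
  } else if (model == "exponential3") {
    nm <- c("a", "k", "g")
    k0 <- if (ybar0 > 0 && (ybar0 + span) > 0) log((ybar0 + span) / ybar0) else sign(span)
    starts <- lapply(c(1, 2, 4), function(g) c(a = ybar0, k = k0, g = g))
    res <- .fit_sse(obj_for(nm), starts,
                    lower = c(1e-12, -50, 1), upper = c(Inf, 50, 18))
  } else if (model == "hill") {
    nm <- c("a", "v", "kd", "g")
    starts <- unlist(lapply(c(0.05, 0.3, 1), function(kd)
      lapply(c(1, 2, 5), function(g) c(a = ybar0, v = span, kd = kd, g = g))),
      recursive = FALSE)
    res <- .fit_sse(obj_for(nm), starts,
                    lower = c(-Inf, -Inf, 1e-6, 1), upper = c(Inf, Inf, 10, 18))
  } else stop("unknown model: ", model, call. = FALSE)

  if (is.null(res)) {
    return(list(params = NULL, sse = NA_real_, converged = FALSE,
                npar_mean = length(nm)))
  }
  params <- res$par
  names(params) <- nm
  list(params = params, sse = res$value,
       converged = res$convergence == 0, npar_mean = length(nm))
}

#' Fit candidate dose-response models and rank them by AIC
#'
#' Fits the requested mean models to individual observations under a
#' constant-variance Gaussian likelihood and returns them sorted by AIC
#' (smaller is better; the variance parameter is counted). Candidates follow
#' standard benchmark-dose practice for continuous data: `linear`,
#' `power` (exponent restricted to >= 1), `polynomial2`,
#' `exponential3` (background times an exponential in dose^g), and `hill`
#' (background, maximum change, half-maximal dose, power >= 1; the power
#' restriction avoids unbounded low-dose steepness).
#'
#' Models that fail to converge are returned with `converged = FALSE` rather
#' than dropped, so a report can show the failure. Hill and exponential fits
#' require at least four distinct dose levels; with fewer they are flagged as
#' failed with status `"insufficient_dose_levels"`.
#'
#' @inheritParams fit_linear
#' @param models Character vector of model names, a subset of
#'   `c("linear", "power", "polynomial2", "exponential3", "hill")`.
#' @return A list of `curve_fit` objects (class `curve_fit_list`), sorted by
#'   AIC with non-converged fits last. Each element carries `model`, `params`
#'   (on the internal unit-dose scale), `logLik`, `AIC`, `converged`,
#'   `status`, and `mean_fun` (a function of natural-scale dose).
#' @export
fit_candidates <- function(doses, responses, models = .curve_models) {
  stopifnot(is.numeric(doses), is.numeric(responses),
            length(doses) == length(responses))
  models <- match.arg(models, .curve_models, several.ok = TRUE)
  keep <- !is.na(responses) & !is.na(doses)
  doses <- doses[keep]; responses <- responses[keep]
  n_levels <- length(unique(doses))
  if (n_levels < 2) stop("degenerate design: need >= 2 distinct dose levels", call. = FALSE)
  dmax <- max(doses)
  u <- doses / dmax
  n <- length(responses)

  fits <- lapply(models, function(m) {
    if (m %in% c("hill", "exponential3") && n_levels < 4) {
      return(structure(list(model = m, params = NULL, logLik = NA_real_,
                            AIC = NA_real_, converged = FALSE,
                            status = "insufficient_dose_levels",
                            mean_fun = NULL, dmax = dmax,
                            data = list(doses = doses, responses = responses)),
                       class = "curve_fit"))
    }
    r <- .fit_one_model(m, u, responses)
    if (is.null(r$params)) {
      return(structure(list(model = m, params = NULL, logLik = NA_real_,
                            AIC = NA_real_, converged = FALSE,
                            status = "non_convergence",
                            mean_fun = NULL, dmax = dmax,
                            data = list(doses = doses, responses = responses)),
                       class = "curve_fit"))
    }
    ll <- .loglik_const_var(r$sse, n)
    k <- r$npar_mean + 1  # + residual variance
    mf_scaled <- .mean_fun_scaled(m, as.list(r$params))
    structure(list(model = m, params = r$params, logLik = ll,
                   AIC = 2 * k - 2 * ll,
                   converged = r$converged,
                   status = if (r$converged) "ok" else "non_convergence",
                   mean_fun = function(d) mf_scaled(d / dmax),
                   dmax = dmax, npar_mean = r$npar_mean, sse = r$sse,
                   data = list(doses = doses, responses = responses)),
              class = "curve_fit")
  })
  ord <- order(!vapply(fits, `[[`, TRUE, "converged"),
               vapply(fits, function(f) ifelse(is.na(f$AIC), Inf, f$AIC), 0))
  structure(fits[ord], class = "curve_fit_list")
}

#' @export
print.curve_fit <- function(x, ...) {
  cat(sprintf("curve_fit <%s>: %s", x$model,
              if (x$converged) sprintf("AIC %.1f", x$AIC) else x$status), "\n")
  invisible(x)
}

#' @export
print.curve_fit_list <- function(x, ...) {
  cat("Candidate dose-response fits (AIC ascending):\n")
  for (f in x) {
    cat(sprintf("  %-13s %s\n", f$model,
                if (f$converged) sprintf("AIC %9.2f  logLik %9.2f", f$AIC, f$logLik)
                else paste0("FAILED: ", f$status)))
  }
  invisible(x)
}

# ---- benchmark dose -------------------------------------------------------

# wrap a linear_dr_fit so the BMD machinery sees a uniform interface
.as_bmd_fit <- function(fit) {
  if (inherits(fit, "curve_fit")) {
    if (!fit$converged) stop("cannot compute a BMD from a non-converged fit", call. = FALSE)
    return(fit)
  }
  if (inherits(fit, "linear_dr_fit")) {
    a <- fit$a; b <- fit$b
    out <- list(model = "linear",
                params = c(a = a, b = b),
                mean_fun = function(d) a + b * d,
                dmax = 1, npar_mean = 2, converged = TRUE,
                data = fit$data)
    if (!is.null(fit$data)) {
      sse <- sum((fit$data$responses - out$mean_fun(fit$data$doses))^2)
      out$sse <- sse
      out$logLik <- .loglik_const_var(sse, length(fit$data$responses))
      out$AIC <- 2 * 3 - 2 * out$logLik
    } else {
      out$logLik <- NA_real_; out$AIC <- NA_real_
    }
    return(structure(out, class = "curve_fit"))
  }
  stop("`fit` must be a curve_fit or linear_dr_fit", call. = FALSE)
}

# For a trial BMD (scaled dose u0), eliminate one mean parameter using the
# benchmark constraint m(0) - m(u0) = s*delta (s = -1 for decrease), then
# minimise the SSE over the remaining free parameters. Returns the profile
# log-likelihood, or -Inf when the constraint is infeasible.
.profile_loglik <- function(model, u, y, u0, delta, sign_change, params_hat) {
  n <- length(y)
  sse_for <- function(params) {
    mu <- .mean_fun_scaled(model, as.list(params))(u)
    if (any(!is.finite(mu))) return(NA_real_)
    sum((y - mu)^2)
  }
  target <- sign_change * delta  # m(u0) - m(0)

  if (model == "linear") {
    b <- target / u0
    a <- mean(y - b * u)
    return(.loglik_const_var(sse_for(c(a = a, b = b)), n))
  }
  if (model == "polynomial2") {
    # b1*u0 + b2*u0^2 = target -> b1 = (target - b2*u0^2)/u0 ; free: a, b2
    obj <- function(p) {
      b1 <- (target - p[2] * u0^2) / u0
      s <- sse_for(c(a = p[1], b1 = b1, b2 = p[2]))
      if (is.na(s)) 1e300 else s
    }
    res <- .fit_sse(obj, list(c(params_hat[["a"]], params_hat[["b2"]])),
                    lower = c(-Inf, -Inf), upper = c(Inf, Inf))
    if (is.null(res)) return(-Inf)
    return(.loglik_const_var(res$value, n))
  }
  if (model == "power") {
    # b*u0^g = target ; free: a, g
    obj <- function(p) {
      b <- target / u0^p[2]
      s <- sse_for(c(a = p[1], b = b, g = p[2]))
      if (is.na(s)) 1e300 else s
    }
    res <- .fit_sse(obj, list(c(params_hat[["a"]], params_hat[["g"]])),
                    lower = c(-Inf, 1), upper = c(Inf, 18))
    if (is.null(res)) return(-Inf)
    return(.loglik_const_var(res$value, n))
  }
  if (model == "exponential3") {
    # a*(exp(k*u0^g) - 1) = target -> k = log(1 + target/a)/u0^g ; free: a, g
    obj <- function(p) {
      if (1 + target / p[1] <= 0) return(1e300)
      k <- log(1 + target / p[1]) / u0^p[2]
      s <- sse_for(c(a = p[1], k = k, g = p[2]))
      if (is.na(s)) 1e300 else s
    }
    res <- .fit_sse(obj, list(c(params_hat[["a"]], params_hat[["g"]])),
                    lower = c(1e-12, 1), upper = c(Inf, 18))
    if (is.null(res)) return(-Inf)
    return(.loglik_const_var(res$value, n))
  }
  if (model == "hill") {
    # v*u0^g/(kd^g + u0^g) = target -> v = target*(kd^g + u0^g)/u0^g ; free: a, kd, g
    obj <- function(p) {
      v <- target * (p[2]^p[3] + u0^p[3]) / u0^p[3]
      s <- sse_for(c(a = p[1], v = v, kd = p[2], g = p[3]))
      if (is.na(s)) 1e300 else s
    }
    res <- .fit_sse(obj, list(c(params_hat[["a"]], params_hat[["kd"]], params_hat[["g"]])),
                    lower = c(-Inf, 1e-6, 1), upper = c(Inf, 10, 18))
    if (is.null(res)) return(-Inf)
    return(.loglik_const_var(res$value, n))
  }
  -Inf
}

#' Benchmark dose at an SD-based benchmark response
#'
#' Computes the benchmark dose (BMD): the dose at which the fitted mean shifts
#' from its dose-0 prediction by `bmr_sd` control standard deviations in the
#' adverse direction. The BMDL is the one-sided 95% profile-likelihood lower
#' bound (chi-squared 1 df at the 90% two-sided cutoff, the standard
#' benchmark-dose convention); when profiling fails, a delta-method bound is
#' substituted and flagged in `bmdl_method`.
#'
#' A quality flag `"questionable_extrapolation"` is raised when the BMD falls
#' more than three-fold below the lowest nonzero dose in the data, the usual
#' symptom of a model (typically Hill) extrapolating steep low-dose behaviour
#' the design cannot support.
#'
#' @param fit A `curve_fit` (from [fit_candidates()]) or a [linear_dr_fit]
#'   with data attached (from [fit_linear()]). BMDL and the scaled residual
#'   require attached data.
#' @param control_mean Observed control-group mean (endpoint units). Used for
#'   reporting; the benchmark shift is measured from the model's dose-0
#'   prediction.
#' @param control_sd Control-group standard deviation (endpoint units), > 0.
#' @param bmr_sd Benchmark response as a multiple of `control_sd` (default 1).
#' @param direction `"decrease"` (default; swim bladder area, body length) or
#'   `"increase"` (yolk sac area).
#' @return An object of class `bmd_result`: model name, `bmr_sd`, `bmd`,
#'   `bmdl`, `aic`, `scaled_residual` (at the dose group nearest the BMD),
#'   `qc_flag`, `status` (`"ok"` or `"no_solution"`), and `bmdl_method`.
#' @examples
#' d <- rep(c(0, 10, 100, 1000, 2000), each = 20)
#' set.seed(1)
#' y <- 0.06 - 1e-5 * d + rnorm(length(d), sd = 0.01)
#' f <- fit_linear(d, y)
#' compute_bmd(f, control_mean = f$R0, control_sd = f$control_sd)
#' @export
compute_bmd <- function(fit, control_mean, control_sd, bmr_sd = 1,
                        direction = c("decrease", "increase")) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(control_sd), length(control_sd) == 1, control_sd > 0,
            is.numeric(bmr_sd), bmr_sd > 0)
  bf <- .as_bmd_fit(fit)
  delta <- bmr_sd * control_sd
  sign_change <- if (direction == "decrease") -1 else +1
  m0 <- bf$mean_fun(0)
  have_data <- !is.null(bf$data)
  dmax <- if (have_data) max(bf$data$doses) else NA_real_

  # --- BMD ---
  bmd <- NA_real_
  if (bf$model == "linear") {
    b_nat <- bf$params[["b"]] / bf$dmax
    if (sign(b_nat) == sign_change && b_nat != 0) bmd <- delta / abs(b_nat)
  } else {
    f <- function(d) (bf$mean_fun(d) - m0) - sign_change * delta
    hi <- 10 * dmax
    # walk up a geometric grid to find the first sign change
    grid <- c(0, dmax * 10^seq(-6, 1, length.out = 200))
    vals <- vapply(grid, f, 0)
    cross <- which(vals[-1] * vals[-length(vals)] <= 0 & is.finite(vals[-1]))[1]
    if (!is.na(cross)) {
      lo <- grid[cross]; up <- grid[cross + 1]
      if (lo == up) bmd <- lo
      else bmd <- stats::uniroot(f, c(lo, up), tol = 1e-12 * max(1, up))$root
    } else if (f(hi) * f(1e-12 * dmax) < 0) {
      bmd <- stats::uniroot(f, c(1e-12 * dmax, hi), tol = 1e-10 * hi)$root
    }
  }
  if (!is.na(bmd) && !is.na(dmax) && bmd > 10 * dmax) bmd <- NA_real_
  if (is.na(bmd) || bmd <= 0) {
    return(structure(list(model = bf$model, bmr_sd = bmr_sd, direction = direction,
                          bmd = NA_real_, bmdl = NA_real_, aic = bf$AIC,
                          scaled_residual = NA_real_, qc_flag = NA_character_,
                          status = "no_solution", bmdl_method = "none"),
                     class = "bmd_result"))
  }

  # --- BMDL by profile likelihood ---
  bmdl <- NA_real_
  bmdl_method <- "none"
  if (have_data) {
    u <- bf$data$doses / bf$dmax
    y <- bf$data$responses
    ll_hat <- bf$logLik
    cutoff <- stats::qchisq(0.90, df = 1) / 2
    gfun <- function(bmd0) {
      (ll_hat - .profile_loglik(bf$model, u, y, bmd0 / bf$dmax, delta,
                                sign_change, bf$params)) - cutoff
    }
    lo <- bmd
    found <- FALSE
    for (i in 1:14) {
      lo <- lo / 2
      gv <- tryCatch(gfun(lo), error = function(e) NA_real_)
      if (is.finite(gv) && gv >= 0) { found <- TRUE; break }
    }
    if (found) {
      bmdl <- tryCatch(
        stats::uniroot(gfun, c(lo, bmd), tol = 1e-9 * bmd)$root,
        error = function(e) NA_real_)
      if (!is.na(bmdl)) bmdl_method <- "profile"
    }
    if (is.na(bmdl) && bf$model == "linear") {
      # delta-method fallback on the slope
      x <- bf$data$doses
      n <- length(y)
      b_nat <- bf$params[["b"]] / bf$dmax
      s2 <- bf$sse / (n - 2)
      se_b <- sqrt(s2 / sum((x - mean(x))^2))
      se_bmd <- delta / b_nat^2 * se_b
      bmdl <- max(bmd - stats::qnorm(0.95) * se_bmd, .Machine$double.eps)
      bmdl_method <- "delta_fallback"
    }
    if (!is.na(bmdl)) bmdl <- min(bmdl, bmd)
  }

  # --- scaled residual at the dose group nearest the BMD ---
  scaled_resid <- NA_real_
  qc <- NA_character_
  if (have_data) {
    dl <- sort(unique(bf$data$doses))
    near <- dl[which.min(abs(dl - bmd))]
    yg <- bf$data$responses[bf$data$doses == near]
    sigma_mle <- sqrt(bf$sse / length(bf$data$responses))
    scaled_resid <- (mean(yg) - bf$mean_fun(near)) / (sigma_mle / sqrt(length(yg)))
    lowest_nonzero <- min(dl[dl > 0])
    qc <- if (bmd < lowest_nonzero / 3) "questionable_extrapolation" else "ok"
  }

  structure(list(model = bf$model, bmr_sd = bmr_sd, direction = direction,
                 bmd = bmd, bmdl = bmdl, aic = bf$AIC,
                 scaled_residual = scaled_resid, qc_flag = qc,
                 status = "ok", bmdl_method = bmdl_method),
            class = "bmd_result")
}

#' @export
print.bmd_result <- function(x, ...) {
  cat(sprintf("BMD result (%s model, BMR = %g control SD, %s):\n",
              x$model, x$bmr_sd, x$direction))
  if (x$status != "ok") { cat("  status:", x$status, "\n"); return(invisible(x)) }
  cat(sprintf("  BMD  %.4g ug/L\n  BMDL %.4g ug/L (%s)\n", x$bmd, x$bmdl, x$bmdl_method))
  if (!is.na(x$aic)) cat(sprintf("  AIC  %.2f\n", x$aic))
  if (!is.na(x$scaled_residual))
    cat(sprintf("  scaled residual near BMD: %.3f\n", x$scaled_residual))
  if (!is.na(x$qc_flag)) cat("  qc:", x$qc_flag, "\n")
  invisible(x)
}

#' Tidy a set of BMD results into a report table
#'
#' @param results A list of `bmd_result` objects (e.g. one per candidate
#'   model).
#' @return A tibble with one row per model: `model`, `bmd`, `bmdl`, `aic`,
#'   `scaled_residual`, `qc_flag`, `status`.
#' @export
bmd_report <- function(results) {
  stopifnot(all(vapply(results, inherits, TRUE, "bmd_result")))
  dplyr::bind_rows(lapply(results, function(r) {
    tibble::tibble(model = r$model, bmd = r$bmd, bmdl = r$bmdl, aic = r$aic,
                   scaled_residual = r$scaled_residual,
                   qc_flag = r$qc_flag %||% NA_character_, status = r$status)
  }))
}

#' Drop a non-monotonic top dose group before curve fitting
#'
#' A flat or monotone response followed by a sharp reversal at the highest
#' dose precludes sensible dose-response modelling; the standard remedy is to
#' exclude the top group. The top group is dropped if and only if its mean
#' reverses the direction of the preceding trend by more than one control
#' standard deviation.
#'
#' @param group_means Numeric vector of group mean responses, ordered by
#'   increasing dose (control first). At least 3 groups.
#' @param control_sd Control-group standard deviation, > 0.
#' @return An integer vector of retained group indices, with attribute
#'   `"dropped_top"` (logical). The decision is reported via [message()].
#' @examples
#' exclude_nonmonotonic_top(c(0.064, 0.063, 0.063, 0.062, 0.046, 0.075), 0.013)
#' @export
exclude_nonmonotonic_top <- function(group_means, control_sd) {
  stopifnot(is.numeric(group_means), is.numeric(control_sd), control_sd > 0)
  k <- length(group_means)
  if (k < 3) stop("need at least 3 dose groups to assess the top group", call. = FALSE)
  trend <- sign(group_means[k - 1] - group_means[1])
  if (trend == 0) trend <- sign(sum(diff(group_means[seq_len(k - 1)])))
  last_step <- group_means[k] - group_means[k - 1]
  drop <- trend != 0 && sign(last_step) == -trend && abs(last_step) > control_sd
  retained <- if (drop) seq_len(k - 1) else seq_len(k)
  message(if (drop) {
    sprintf("top dose group excluded: mean reverses the preceding trend by %.3g (> 1 control SD = %.3g)",
            abs(last_step), control_sd)
  } else {
    "all dose groups retained"
  })
  structure(retained, dropped_top = drop)
}
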