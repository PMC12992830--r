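#' Four-parameter logistic dose-response curve
#'
#' Predicted response (% of vehicle control) at a given dose.  The model is
#' the standard four-parameter logistic on log10 dose,
#' \deqn{Y = bottom + (top - bottom) / (1 + 10^{(X - \log_{10} IC) \cdot h}},
#' parameterized so that a positive Hill coefficient `hill` describes an
#' *inhibition* curve: the response declines from `top` (low dose) to
#' `bottom` (high dose), and `log_ic` is the log10 dose of the curve's
#' midpoint.  At dose 0 the predicted response is `top` (the vehicle
#' anchor); dose 0 is excluded from fitting because its log dose is
#' undefined.
#'
#' @param dose_uM dose in uM (vectorized, zero allowed).
#' @param top,bottom upper/lower asymptotes, % of control.
#' @param hill Hill coefficient (positive for falling curves).
#' @param log_ic log10 of the midpoint dose in uM.
#' @return predicted responses, % of control.
#' @examples
#' fourpl(10, top = 100, bottom = 0, hill = 1, log_ic = 1)  # midpoint: 50
#' @export
fourpl <- function(dose_uM, top, bottom, hill, log_ic) {
  x <- suppressWarnings(log10(dose_uM))
  bottom + (top - bottom) / (1 + 10^((x - log_ic) * hill))
}

#' Normalize assay readouts to the vehicle control
#'
#' Linear rescaling so that the vehicle-control mean maps to 100%.
#'
#' @param responses raw readouts (TEER in Ohm.cm2 or ATP luminescence).
#' @param control_mean mean vehicle-control readout (must be positive).
#' @return responses in % of control.
#' @export
normalize_to_control <- function(responses, control_mean) {
  if (!is.finite(control_mean) || control_mean <= 0) {
    abort("control_mean must be a positive number")
  }
  responses / control_mean * 100
}

#' Percent reduction at the top tested dose
#'
#' The drug-effect summary used for classification:
#' `(control - value at top dose) / control * 100`.  Negative values mean
#' the treated readout exceeded the vehicle control.
#'
#' @param control_value vehicle-control readout (positive).
#' @param value_at_top_dose readout at the highest tested dose (100 uM on
#'   the bundled panel's grid).
#' @return signed percentage.
#' @examples
#' percent_reduction(100, 10)      # 90
#' percent_reduction(100, 108.14)  # -8.14
#' @export
percent_reduction <- function(control_value, value_at_top_dose) {
  if (any(!is.finite(control_value)) || any(control_value <= 0)) {
    abort("control_value must be positive")
  }
  (control_value - value_at_top_dose) / control_value * 100
}

#' Default parameter box for 4PL fitting
#'
#' Bounds that stabilize the optimizer on sparse 6-point dose grids:
#' the top asymptote near the normalization anchor, a bottom that may sit
#' anywhere below it (slightly negative values tolerate overshoot in noisy
#' normalized data), Hill coefficients between 0.1 and 10, and midpoints
#' between 1 nM and 10 mM.
#'
#' @return a list with elements `top`, `bottom`, `hill`, `log_ic`, each a
#'   length-2 numeric `c(lower, upper)`.
#' @export
fourpl_bounds <- function() {
  list(top = c(80, 120), bottom = c(-10, 100),
       hill = c(0.1, 10), log_ic = c(-3, 4))
}

.fourpl_sse <- function(par, x, y) {
  p <- fourpl(10^x, par[1], par[2], par[3], par[4])
  sum((y - p)^2)
}

#' Fit a four-parameter logistic model to a dose-response series
#'
#' Least-squares fit of [fourpl()] to responses normalized to % of vehicle
#' control.  The vehicle (dose 0) is excluded from the log-dose fit and
#' serves only as the normalization anchor.  By default replicates are
#' averaged per dose before fitting.  Fitting uses Levenberg-Marquardt
#' least squares within a parameter box (see [fourpl_bounds()]); if that
#' fails to converge, a coarse grid search over the box followed by
#' box-constrained quasi-Newton refinement is used as a fallback.
#'
#' A fit whose span `top - bottom` is smaller than `span_min` percentage
#' points is flagged *non-informative*: the data carry no usable
#' dose-response signal and downstream IC interpolation censors both ICs.
#'
#' @param series a data frame with columns `dose_uM` and `response`
#'   (% of control), one row per replicate measurement, e.g. from
#'   [generate_series()] after normalization.
#' @param bounds parameter box, as [fourpl_bounds()].
#' @param start optional named list/vector of starting values
#'   (`top`, `bottom`, `hill`, `log_ic`); a data-driven heuristic is used
#'   when `NULL`.
#' @param use fit on per-dose `"means"` (default) or on all
#'   `"replicates"`.
#' @param span_min minimum informative span, percentage points.
#' @return an object of class `fourpl_fit`: a list with elements `top`,
#'   `bottom`, `hill`, `log_ic`, `residual_sse`, `converged`,
#'   `non_informative`, `n_doses`.
#' @examples
#' d <- c(1, 5, 10, 50, 100)
#' series <- data.frame(dose_uM = d,
#'                      response = fourpl(d, 100, 0, 1, 1))
#' fit_4pl(series)
#' @export
fit_4pl <- function(series, bounds = fourpl_bounds(), start = NULL,
                    use = c("means", "replicates"), span_min = 5) {
  use <- match.arg(use)
  series <- as.data.frame(series)
  if (!all(c("dose_uM", "response") %in% names(series))) {
    abort("series needs columns dose_uM and response")
  }
  if (any(!is.finite(series$response))) {
    abort("non-finite responses in series")
  }
  dat <- series[series$dose_uM > 0, , drop = FALSE]
  if (length(unique(dat$dose_uM)) < 2) {
    abort("insufficient data: need at least 2 distinct non-vehicle doses")
  }
  if (use == "means") {
    agg <- stats::aggregate(response ~ dose_uM, dat, mean)
  } else {
    agg <- dat[, c("dose_uM", "response")]
  }
  x <- log10(agg$dose_uM)
  y <- agg$response
  lo <- vapply(bounds, `[`, numeric(1), 1L)
  hi <- vapply(bounds, `[`, numeric(1), 2L)

  clamp <- function(v, a, b) pmin(pmax(v, a), b)
  if (is.null(start)) {
    top0 <- clamp(max(y), lo["top"], hi["top"])
    bot0 <- clamp(min(y), lo["bottom"], hi["bottom"])
    mid <- (top0 + bot0) / 2
    log_ic0 <- clamp(x[which.min(abs(y - mid))], lo["log_ic"], hi["log_ic"])
    start <- c(top = top0, bottom = bot0, hill = 1, log_ic = log_ic0)
  } else {
    start <- unlist(start)[c("top", "bottom", "hill", "log_ic")]
  }

  run_lm <- function(st) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ fourpl(10^x, top, bottom, hill, log_ic),
        start = as.list(st), lower = lo, upper = hi,
        control = minpack.lm::nls.lm.control(
          maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    list(par = stats::coef(fit)[c("top", "bottom", "hill", "log_ic")],
         sse = sum(stats::resid(fit)^2))
  }

  converged <- FALSE
  par <- start
  sse <- .fourpl_sse(start, x, y)
  best <- run_lm(start)
  if (!is.null(best)) {
    par <- best$par
    sse <- best$sse
    converged <- TRUE
  }
  # the 6-point grid gives Levenberg-Marquardt little to work with when
  # the transition sits near the grid edge; retry from alternative Hill
  # starts unless the first fit is already essentially exact
  if (sse > 1e-8) {
    for (h in c(0.5, 2, 4)) {
      alt <- run_lm(replace(start, "hill", min(max(h, lo["hill"]), hi["hill"])))
      if (!is.null(alt) && alt$sse < sse) {
        par <- alt$par
        sse <- alt$sse
        converged <- TRUE
      }
    }
  }
  if (!converged) {
    # fallback: coarse grid over the box, then box-constrained refinement
    grid <- expand.grid(
      top = clamp(max(y), lo["top"], hi["top"]),
      bottom = seq(lo["bottom"], min(hi["bottom"], max(y)), length.out = 8),
      hill = c(0.25, 0.5, 1, 2, 4),
      log_ic = seq(max(lo["log_ic"], min(x) - 1),
                   min(hi["log_ic"], max(x) + 1), length.out = 12))
    gsse <- apply(grid, 1, .fourpl_sse, x = x, y = y)
    cand <- as.numeric(grid[which.min(gsse), ])
    opt <- stats::optim(cand, .fourpl_sse, x = x, y = y,
                        method = "L-BFGS-B", lower = lo, upper = hi,
                        control = list(maxit = 1000, factr = 1e4))
    if (opt$value < sse) {
      par <- setNames(opt$par, c("top", "bottom", "hill", "log_ic"))
      sse <- opt$value
      converged <- opt$convergence == 0
    }
  }
  if (converged && sse > 0 && sse < 1e-2) {
    # near-noiseless data: polish away the ~1e-4 parameter error left by
    # the Levenberg-Marquardt stopping rule
    pol <- stats::optim(par, .fourpl_sse, x = x, y = y,
                        method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-16))
    inside <- all(pol$par >= lo - 1e-9) && all(pol$par <= hi + 1e-9)
    if (pol$value < sse && inside) {
      par <- setNames(pmin(pmax(pol$par, lo), hi),
                      c("top", "bottom", "hill", "log_ic"))
      sse <- pol$value
    }
  }

  structure(list(
    top = unname(par["top"]), bottom = unname(par["bottom"]),
    hill = unname(par["hill"]), log_ic = unname(par["log_ic"]),
    residual_sse = sse, converged = converged,
    non_informative = !converged ||
      (par["top"] - par["bottom"]) < span_min,
    n_doses = length(unique(agg$dose_uM))
  ), class = "fourpl_fit")
}

#' @export
print.fourpl_fit <- function(x, ...) {
  cat(sprintf(
    "<fourpl_fit> top=%.2f bottom=%.2f hill=%.3f log_ic=%.3f (IC=%.3g uM)\n",
    x$top, x$bottom, x$hill, x$log_ic, 10^x$log_ic))
  cat(sprintf("  SSE=%.4g, converged=%s%s\n", x$residual_sse, x$converged,
              if (x$non_informative) ", non-informative" else ""))
  invisible(x)
}

#' @export
predict.fourpl_fit <- function(object, dose_uM, ...) {
  fourpl(dose_uM, object$top, object$bottom, object$hill, object$log_ic)
}

#' Interpolate an IC value from a fitted curve
#'
#' Closed-form inversion of the fitted 4PL for the dose at which the
#' predicted response equals `level_pct` percent of control: IC15
#' corresponds to `level_pct = 85` (a 15% decrement in the normalized
#' readout) and IC50 to `level_pct = 50`.  When the fitted curve never
#' crosses the level within `(0, max_dose_uM]` -- because the level lies
#' outside the fitted asymptotes, the crossing dose exceeds the tested
#' range, or the fit is non-informative -- the IC is right-censored at
#' `max_dose_uM` rather than extrapolated.
#'
#' With `scale = "span"` the level is interpreted relative to the fitted
#' span instead (`bottom + level_pct/100 * (top - bottom)`); the default
#' absolute-control scale is the conventional choice when responses are
#' anchored at 100% vehicle control.
#'
#' @param fit a [fit_4pl()] result.
#' @param level_pct residual response level, % of control, in (0, 100).
#' @param max_dose_uM highest tested dose (censoring limit).
#' @param scale `"control"` (absolute % of control, default) or `"span"`.
#' @return a [censored_conc()].
#' @examples
#' f <- fit_4pl(data.frame(dose_uM = c(1, 5, 10, 50, 100),
#'                         response = fourpl(c(1, 5, 10, 50, 100),
#'                                           100, 0, 1, 1)))
#' interpolate_ic(f, 50)  # 10 uM
#' interpolate_ic(f, 85)  # ~1.765 uM
#' @export
interpolate_ic <- function(fit, level_pct, max_dose_uM = 100,
                           scale = c("control", "span")) {
  stopifnot(inherits(fit, "fourpl_fit"),
            level_pct > 0, level_pct < 100)
  scale <- match.arg(scale)
  censored <- censored_conc(censored = TRUE, limit_uM = max_dose_uM)
  if (fit$non_informative || !fit$converged) return(censored)
  level <- if (scale == "control") level_pct else
    fit$bottom + level_pct / 100 * (fit$top - fit$bottom)
  if (level <= fit$bottom || level >= fit$top) return(censored)
  x <- fit$log_ic +
    log10((fit$top - level) / (level - fit$bottom)) / fit$hill
  dose <- 10^x
  if (!is.finite(dose) || dose <= 0 || dose > max_dose_uM) return(censored)
  censored_conc(value_uM = dose, limit_uM = max_dose_uM)
}
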