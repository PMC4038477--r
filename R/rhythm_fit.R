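#' Fit a damped cosine to a detrended trace
#'
#' Least-squares fit of the damped cosinor model
#' \deqn{y(t) = m + A e^{-\lambda t} \cos(2\pi (t - \phi)/\tau)}
#' to a bioluminescence trace. For fixed period and damping the model is
#' linear in the mesor and the cosine/sine coefficients, so the fit uses
#' variable projection: `optim` searches over \eqn{(\tau, \lambda)} while
#' the linear block is solved exactly, started from a multistart grid of
#' candidate periods. Ties in residual sum of squares are broken toward
#' the smallest period.
#'
#' @param trace A [lumi_trace()], normally detrended (unit mean). Fitting
#'   a raw trace requires `allow_raw = TRUE`.
#' @param tau_grid Multistart period grid in hours.
#' @param fix_lambda If `TRUE`, damping is pinned to 0 (pure cosinor).
#' @param allow_raw Permit fitting a trace not flagged as detrended.
#' @return An object of class `rhythm_fit`: list with `tau_h`, `amplitude`
#'   (envelope at t = 0), `phase_h` (first fitted peak after
#'   synchronization, in `[0, tau)`), `damping_per_h`, `mesor`, `r2`,
#'   `converged` and `diagnostics`.
#' @export
#' @examples
#' t <- seq(0, 120, by = 1 / 6)
#' y <- 1 + 0.4 * exp(-0.005 * t) * cos(2 * pi * (t - 16.6) / 24.2)
#' fit <- fit_damped_cosine(lumi_trace(t, y, detrended = TRUE))
#' round(c(fit$tau_h, fit$amplitude, fit$phase_h), 3)
fit_damped_cosine <- function(trace, tau_grid = c(20, 22, 24, 26, 28),
                              fix_lambda = FALSE, allow_raw = FALSE) {
  stopifnot(inherits(trace, "lumi_trace"))
  if (!trace$meta$detrended && !allow_raw)
    stop("trace is not detrended; pass allow_raw = TRUE to fit anyway",
         call. = FALSE)
  t <- trace$time_h
  y <- trace$value
  if (t[length(t)] - t[1] < 48)
    stop("rhythm fitting needs at least 48 h of record", call. = FALSE)

  tss <- sum((y - mean(y))^2)

  # exact linear solve for (m, B, C) given (tau, lambda); returns RSS + coef
  proj <- function(tau, lambda) {
    env <- exp(-lambda * t)
    X <- cbind(1, env * cos(2 * pi * t / tau), env * sin(2 * pi * t / tau))
    fit <- tryCatch(stats::lm.fit(X, y), error = function(e) NULL)
    if (is.null(fit)) return(list(rss = Inf))
    rss <- sum(fit$residuals^2)
    list(rss = rss, coef = fit$coefficients)
  }
  obj <- function(par) {
    tau <- par[1]
    lambda <- if (fix_lambda) 0 else par[2]
    if (tau <= 4 || lambda < 0) return(1e12)
    proj(tau, lambda)$rss
  }

  best <- NULL
  for (tau0 in sort(tau_grid)) {
    par0 <- if (fix_lambda) tau0 else c(tau0, 0.005)
    res <- tryCatch(
      if (fix_lambda)
        stats::optim(par0, obj, method = "Brent",
                     lower = max(4.1, tau0 - 6), upper = tau0 + 6)
      else
        stats::optim(par0, obj, method = "L-BFGS-B",
                     lower = c(max(4.1, tau0 - 6), 0),
                     upper = c(tau0 + 6, 0.5),
                     control = list(factr = 1e4)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value - 1e-12 ||
        (abs(res$value - best$value) <= 1e-12 && res$par[1] < best$par[1]))
      best <- res
  }

  if (is.null(best) || !is.finite(best$value)) {
    return(structure(
      list(tau_h = NA_real_, amplitude = NA_real_, phase_h = NA_real_,
           damping_per_h = NA_real_, mesor = NA_real_, r2 = NA_real_,
           converged = FALSE,
           diagnostics = "no multistart converged"),
      class = "rhythm_fit"))
  }

  tau <- best$par[1]
  lambda <- if (fix_lambda) 0 else best$par[2]
  pj <- proj(tau, lambda)
  B <- pj$coef[2]; C <- pj$coef[3]
  A <- sqrt(B^2 + C^2)
  phase <- (atan2(C, B) * tau / (2 * pi)) %% tau
  r2 <- if (tss > 0) 1 - pj$rss / tss else 0
  structure(
    list(tau_h = tau, amplitude = unname(A), phase_h = unname(phase),
         damping_per_h = lambda, mesor = unname(pj$coef[1]), r2 = r2,
         converged = TRUE, diagnostics = NULL),
    class = "rhythm_fit")
}

#' @export
print.rhythm_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<rhythm_fit> not converged:", x$diagnostics, "\n")
  } else {
    cat(sprintf(
      "<rhythm_fit> tau = %.2f h, A = %.3f, phase = %.2f h, lambda = %.4f/h, r2 = %.3f\n",
      x$tau_h, x$amplitude, x$phase_h, x$damping_per_h, x$r2))
  }
  invisible(x)
}

#' Classify an oscillator as strong or weak
#'
#' A cell line counts as a strong oscillator when its fitted rhythm shows
#' a clear circadian period and a relative amplitude of at least 20\% of
#' the detrended (unit-mean) signal; everything else, including
#' unconverged fits, is weak.
#'
#' @param fit A [fit_damped_cosine()] result.
#' @param min_rel_amplitude Amplitude threshold on the detrended scale
#'   (default 0.20).
#' @param period_band Admissible circadian period range in hours.
#' @param r2_min Minimum coefficient of determination for a "clear"
#'   rhythm (default 0.5).
#' @return An `oscillator_class` list: `label` ("strong"/"weak"),
#'   `reason`, and the thresholds used.
#' @export
classify_oscillator <- function(fit, min_rel_amplitude = 0.20,
                                period_band = c(18, 32), r2_min = 0.5) {
  stopifnot(inherits(fit, "rhythm_fit"))
  mk <- function(label, reason) structure(
    list(label = label, reason = reason,
         rel_amplitude_used = min_rel_amplitude,
         period_band_used = period_band, r2_min_used = r2_min),
    class = "oscillator_class")
  if (!isTRUE(fit$converged)) return(mk("weak", "no fit"))
  if (fit$amplitude < min_rel_amplitude)
    return(mk("weak", sprintf("amplitude %.3f < %.2f", fit$amplitude,
                              min_rel_amplitude)))
  if (fit$tau_h < period_band[1] || fit$tau_h > period_band[2])
    return(mk("weak", sprintf("period %.2f h outside [%g, %g]",
                              fit$tau_h, period_band[1], period_band[2])))
  if (fit$r2 < r2_min)
    return(mk("weak", sprintf("r2 %.3f < %.2f", fit$r2, r2_min)))
  mk("strong", "amplitude, period and fit quality criteria met")
}

#' @export
print.oscillator_class <- function(x, ...) {
  cat(sprintf("<oscillator_class> %s (%s)\n", x$label, x$reason))
  invisible(x)
}
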