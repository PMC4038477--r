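#' Bioluminescence trace container
#'
#' A `lumi_trace` holds a reporter time series sampled at (nominally)
#' uniform intervals: time in hours since synchronization and non-negative
#' luminescence counts (or a unit-mean detrended ratio).
#'
#' @param time_h Numeric vector of hours since synchronization, strictly
#'   increasing and uniformly spaced (within 1\% relative tolerance).
#' @param value Numeric vector of reporter counts, same length as `time_h`.
#' @param cell_line Optional cell-line label.
#' @param detrended Logical; `TRUE` when `value` is a detrended ratio.
#' @param smoothed Logical; `TRUE` when a running-average smoother was applied.
#'
#' @return An object of class `lumi_trace`: a list with elements `time_h`,
#'   `value`, `sampling_per_h` and `meta`.
#' @export
#' @examples
#' tr <- lumi_trace(seq(0, 72, by = 1), rep(5, 73))
#' print(tr)
lumi_trace <- function(time_h, value, cell_line = NA_character_,
                       detrended = FALSE, smoothed = FALSE) {
  time_h <- as.numeric(time_h)
  value <- as.numeric(value)
  if (length(time_h) != length(value))
    stop("time_h and value must have equal length", call. = FALSE)
  if (length(time_h) < 2)
    stop("a trace needs at least 2 samples", call. = FALSE)
  dt <- diff(time_h)
  if (any(dt <= 0))
    stop("time_h must be strictly increasing", call. = FALSE)
  if (max(dt) - min(dt) > 0.01 * mean(dt))
    stop("sampling must be uniform within 1% tolerance", call. = FALSE)
  structure(
    list(time_h = time_h, value = value,
         sampling_per_h = 1 / mean(dt),
         meta = list(cell_line = cell_line, detrended = isTRUE(detrended),
                     smoothed = isTRUE(smoothed))),
    class = "lumi_trace")
}

#' @export
print.lumi_trace <- function(x, ...) {
  cat(sprintf(
    "<lumi_trace> %d samples, %.2f-%.2f h, %.3g/h%s%s%s\n",
    length(x$time_h), x$time_h[1], x$time_h[length(x$time_h)],
    x$sampling_per_h,
    if (!is.na(x$meta$cell_line)) paste0(", ", x$meta$cell_line) else "",
    if (x$meta$detrended) ", detrended" else "",
    if (x$meta$smoothed) ", smoothed" else ""))
  invisible(x)
}

# Centered running mean with full windows only (NA where the window would
# be truncated); k must be odd.
.running_mean_full <- function(v, k) {
  n <- length(v)
  out <- rep(NA_real_, n)
  half <- (k - 1L) %/% 2L
  if (n >= k) {
    cs <- cumsum(c(0, v))
    idx <- (half + 1L):(n - half)
    out[idx] <- (cs[idx + half + 1L] - cs[idx - half]) / k
  }
  out
}

#' Detrend a trace by its 24-hour running average
#'
#' Divides raw luminescence counts by a centered running mean over
#' `window_h` hours, the standard normalization for luciferase reporter
#' recordings whose baseline decays as luciferin is consumed. The first and
#' last half-window, where a full centered window is unavailable, are
#' trimmed from the output.
#'
#' @param trace A [lumi_trace()].
#' @param window_h Running-average window in hours (default 24, one
#'   circadian cycle, so that the oscillation itself averages out).
#' @return A detrended [lumi_trace()] with unit-mean values, shortened by
#'   `window_h` in total.
#' @export
#' @examples
#' tr <- lumi_trace(0:72, rep(5, 73))
#' dt <- detrend_running_average(tr)
#' range(dt$value) # exactly 1
detrend_running_average <- function(trace, window_h = 24) {
  stopifnot(inherits(trace, "lumi_trace"))
  if (window_h <= 0) stop("window_h must be positive", call. = FALSE)
  span <- trace$time_h[length(trace$time_h)] - trace$time_h[1]
  if (span < 2 * window_h)
    stop(sprintf("trace spans %.1f h; detrending needs >= 2 x window (%.1f h)",
                 span, 2 * window_h), call. = FALSE)
  if (any(trace$value <= 0))
    stop("detrending requires strictly positive counts", call. = FALSE)
  k <- round(window_h * trace$sampling_per_h)
  if (k %% 2 == 0) k <- k + 1L   # symmetric window
  rm <- .running_mean_full(trace$value, k)
  keep <- !is.na(rm)
  lumi_trace(trace$time_h[keep], trace$value[keep] / rm[keep],
             cell_line = trace$meta$cell_line,
             detrended = TRUE, smoothed = trace$meta$smoothed)
}

#' Smooth a trace by a short running average
#'
#' Centered moving mean over `window_h` hours; edge windows shrink
#' symmetrically so no samples are lost (unlike detrending, which trims).
#'
#' @inheritParams detrend_running_average
#' @param window_h Window in hours (default 4).
#' @return A smoothed [lumi_trace()] of identical length.
#' @export
smooth_running_average <- function(trace, window_h = 4) {
  stopifnot(inherits(trace, "lumi_trace"))
  if (window_h <= 0) stop("window_h must be positive", call. = FALSE)
  k <- round(window_h * trace$sampling_per_h)
  if (k %% 2 == 0) k <- k + 1L
  if (k < 3) {
    warning("smoothing window shorter than the sampling interval; ",
            "returning trace unchanged")
    return(trace)
  }
  n <- length(trace$value)
  half <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, trace$value))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  # shrink symmetrically at edges so the window stays centered
  shrink <- pmin(seq_len(n) - lo, hi - seq_len(n))
  lo <- seq_len(n) - shrink
  hi <- seq_len(n) + shrink
  sm <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  lumi_trace(trace$time_h, sm, cell_line = trace$meta$cell_line,
             detrended = trace$meta$detrended, smoothed = TRUE)
}

#' Phase of entrainment from the first post-release peak
#'
#' After temperature entrainment, cells are released to constant
#' conditions and the entrained phase is read as the time from release to
#' the first local maximum of the (detrended, smoothed) reporter trace.
#' The discrete peak is refined by quadratic interpolation through the
#' three samples around it; boundary samples are not eligible peaks.
#'
#' @param trace A [lumi_trace()], ideally detrended and smoothed.
#' @param release_time_h Hour at which constant conditions begin.
#' @param search_window_h How far past release to search (default 36 h).
#' @return Time in hours from release to the first peak.
#' @export
entrainment_phase <- function(trace, release_time_h, search_window_h = 36) {
  stopifnot(inherits(trace, "lumi_trace"))
  t <- trace$time_h
  if (release_time_h < t[1] ||
      release_time_h + search_window_h > t[length(t)])
    stop("trace does not cover [release, release + search_window]",
         call. = FALSE)
  sel <- which(t >= release_time_h & t <= release_time_h + search_window_h)
  v <- trace$value[sel]
  tt <- t[sel]
  n <- length(v)
  peak <- NA_integer_
  for (i in 2:(n - 1)) {
    if (v[i] > v[i - 1] && v[i] >= v[i + 1]) { peak <- i; break }
  }
  if (is.na(peak))
    stop("no local maximum found within the search window", call. = FALSE)
  # quadratic refinement through (i-1, i, i+1)
  y1 <- v[peak - 1]; y2 <- v[peak]; y3 <- v[peak + 1]
  denom <- y1 - 2 * y2 + y3
  offset <- if (abs(denom) < .Machine$double.eps) 0 else
    0.5 * (y1 - y3) / denom
  offset <- max(-0.5, min(0.5, offset))
  dt <- mean(diff(tt))
  tt[peak] + offset * dt - release_time_h
}
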