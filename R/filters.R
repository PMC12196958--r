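#' Zero-phase Butterworth band-pass filter
#'
#' Forward-backward (zero-phase) Butterworth filtering, so that event
#' locations are not shifted in time. The TP-EAR detector uses a 0.5-12 Hz
#' band on the superior-inferior channel to keep the sharp IC/TC impact peaks
#' visible; the baseline detector uses 0.5-5 Hz.
#'
#' @param x numeric vector.
#' @param low_hz,high_hz band edges in Hz; `0 < low_hz < high_hz < fs/2`.
#' @param fs sampling rate in Hz.
#' @param order Butterworth design order (default 4); applied forward and
#'   backward, so the effective attenuation is doubled.
#' @return filtered vector, same length as `x`.
#' @export
bandpass <- function(x, low_hz, high_hz, fs, order = 4L) {
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs / 2)) {
    stop("require 0 < low_hz < high_hz < fs/2", call. = FALSE)
  }
  if (order < 1L) stop("order must be a positive integer", call. = FALSE)
  # a single transfer-function band-pass with a very low relative lower edge
  # is numerically fragile; cascade a gentle high-pass with the low-pass
  hp <- signal::butter(2L, low_hz / (fs / 2), type = "high")
  lp <- signal::butter(order, high_hz / (fs / 2), type = "low")
  filtfilt_padded(lp, filtfilt_padded(hp, as.numeric(x), order = 2L),
                  order = order)
}

# zero-phase filtering with short odd-reflection padding so the filter state
# settles outside the data (as scipy.signal.filtfilt does)
filtfilt_padded <- function(bf, x, order) {
  n <- length(x)
  pad <- min(n - 1L, 3L * (2L * order + 1L))
  if (pad > 0L) {
    left <- 2 * x[1L] - x[(pad + 1L):2L]
    right <- 2 * x[n] - x[(n - 1L):(n - pad)]
    y <- as.numeric(signal::filtfilt(bf, c(left, x, right)))
    y[(pad + 1L):(pad + n)]
  } else {
    as.numeric(signal::filtfilt(bf, x))
  }
}

#' Locate local maxima with a prominence guard
#'
#' Strict local maxima (rising then falling neighbour) whose topographic
#' prominence is at least `min_prominence`. Prominence of a peak is its
#' height above the higher of the two minima separating it from the nearest
#' higher terrain (or the series edge). A guard proportional to the segment's
#' peak-to-peak range suppresses noise wiggles while keeping genuine impact
#' peaks countable.
#'
#' @param x numeric vector.
#' @param min_prominence absolute prominence threshold; if `NULL`, computed
#'   as `prominence_frac * diff(range(x))`.
#' @param prominence_frac fractional fallback for `min_prominence`
#'   (default 0.05).
#' @param min_height optional minimum peak value.
#' @return integer vector of peak indices (1-based), increasing.
#' @export
find_peaks <- function(x, min_prominence = NULL, prominence_frac = 0.05,
                       min_height = -Inf) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  if (is.null(min_prominence)) {
    min_prominence <- prominence_frac * diff(range(x))
  }
  cand <- which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] > x[3:n]) + 1L
  cand <- cand[x[cand] >= min_height]
  if (!length(cand)) return(integer(0))
  keep <- vapply(cand, function(p) {
    peak_prominence(x, p) >= min_prominence
  }, logical(1L))
  cand[keep]
}

# topographic prominence of a local maximum at index p
peak_prominence <- function(x, p) {
  n <- length(x)
  # walk left until strictly higher terrain (or edge); track minimum
  left_min <- x[p]
  i <- p - 1L
  while (i >= 1L && x[i] <= x[p]) {
    if (x[i] < left_min) left_min <- x[i]
    i <- i - 1L
  }
  if (i < 1L) left_min <- min(x[1:p])
  right_min <- x[p]
  i <- p + 1L
  while (i <= n && x[i] <= x[p]) {
    if (x[i] < right_min) right_min <- x[i]
    i <- i + 1L
  }
  if (i > n) right_min <- min(x[p:n])
  x[p] - max(left_min, right_min)
}

#' Locate local minima (used for window closing)
#'
#' @param x numeric vector.
#' @return indices of strict local minima.
#' @keywords internal
local_minima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  which(x[2:(n - 1L)] < x[1:(n - 2L)] & x[2:(n - 1L)] < x[3:n]) + 1L
}

#' Even-derivative peak sharpening
#'
#' Subtracts a weighted, lightly smoothed second difference from the signal:
#' `y = x - w * smooth3(x[i - lag] - 2 x[i] + x[i + lag])`. Because the
#' second difference is large and negative at curvature maxima, subtraction
#' accentuates peaks and can turn a shoulder inflection into a countable
#' local maximum without displacing well-separated maxima. The stencil `lag`
#' sets the feature scale the operator responds to; the default (3 samples,
#' 30 ms at 100 Hz) matches the width of heel-strike and push-off transients.
#'
#' @param segment numeric vector.
#' @param weight sharpening weight (default 1).
#' @param lag second-difference stencil spacing in samples (default 3).
#' @return sharpened vector, same length as `segment`.
#' @export
sharpen_peaks <- function(segment, weight = 1, lag = 3L) {
  x <- as.numeric(segment)
  n <- length(x)
  if (n == 0L) stop("empty segment", call. = FALSE)
  if (n <= 2L * lag + 2L) return(x)
  d2 <- numeric(n)
  idx <- (lag + 1L):(n - lag)
  d2[idx] <- x[idx - lag] - 2 * x[idx] + x[idx + lag]
  # 3-sample smoothing of the curvature estimate
  sm <- stats::filter(d2, rep(1 / 3, 3), sides = 2L)
  sm[is.na(sm)] <- 0
  x - weight * as.numeric(sm)
}

# central-difference gradient with one-sided stencils at the ends
discrete_gradient <- function(x, h = 1) {
  n <- length(x)
  if (n < 2L) return(rep(0, n))
  g <- numeric(n)
  g[1L] <- (x[2L] - x[1L]) / h
  g[n] <- (x[n] - x[n - 1L]) / h
  if (n > 2L) g[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) / (2 * h)
  g
}

# phase unwrapping for a series in degrees
unwrap_deg <- function(x, period = 360) {
  dx <- diff(x)
  jumps <- round(dx / period)
  x - c(0, cumsum(jumps)) * period
}
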