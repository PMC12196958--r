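#' Singular spectrum analysis of a 1-D signal
#'
#' Embeds the signal in a Hankel trajectory matrix of window length `L`,
#' takes its singular value decomposition, and reconstructs each eigentriple
#' back into a 1-D series by anti-diagonal (Hankel) averaging. The
#' reconstructed components are then grouped into `trend` (slow drift),
#' `dominant` (the largest-energy oscillatory pair, typically the fundamental
#' gait oscillation) and `residual`.
#'
#' The default window is 2 s of signal, long enough to separate the gait
#' fundamental from its harmonics even for slow walkers; for short recordings
#' (under 4 s) the window falls back to 1 s so that enough lagged copies
#' remain in the trajectory matrix.
#'
#' The number of retained eigentriples is capped (default 30): gait
#' acceleration concentrates its energy in a few components, and anything
#' beyond the cap is folded into a single residual remainder series so that
#' the stored components still sum exactly to the input signal.
#'
#' @param signal numeric vector.
#' @param fs sampling rate in Hz.
#' @param window_seconds embedding window length in seconds (default 2; an
#'   automatic fallback to 1 applies when `length(signal) < 4 * fs`).
#' @param max_components maximum number of eigentriples reconstructed
#'   individually (default 30).
#' @param trend_max_hz components whose reconstruction holds more than
#'   `trend_energy_frac` of its spectral energy below this frequency (Hz)
#'   count as trend (default 0.5).
#' @param trend_energy_frac see `trend_max_hz` (default 0.95).
#' @param pair_freq_tol relative tolerance within which two components'
#'   dominant frequencies are considered the same harmonic pair (default 0.2).
#' @return An object of class `ssa_decomposition`: `signal`, `fs`,
#'   `window_samples` (L), `components` (n x m matrix, one reconstructed
#'   series per column, ordered by decreasing singular value; a final
#'   remainder column may carry the unreconstructed tail), `singular_values`
#'   (all min(L, K) values), `grouping` (per-column label in
#'   `trend`/`dominant`/`residual`).
#' @seealso [dominant_oscillation()], [trend_removed()]
#' @export
ssa_decompose <- function(signal, fs, window_seconds = 2,
                          max_components = 30L, trend_max_hz = 0.5,
                          trend_energy_frac = 0.95, pair_freq_tol = 0.2) {
  x <- as.numeric(signal)
  n <- length(x)
  if (anyNA(x)) stop("signal contains NA; fill gaps first", call. = FALSE)
  ws <- window_seconds
  if (n < 4 * fs && ws > 1) ws <- 1
  L <- as.integer(round(ws * fs))
  if (n <= L) {
    stop(sprintf("signal too short for SSA: %d samples <= window of %d", n, L),
         call. = FALSE)
  }
  K <- n - L + 1L
  X <- matrix(x[outer(seq_len(L), 0:(K - 1L), `+`)], L, K)
  sv <- svd(X)
  d <- sv$d
  r <- min(as.integer(max_components), sum(d > d[1L] * 1e-12), length(d))
  r <- max(r, 1L)
  w <- pmin(seq_len(n), L, K, n - seq_len(n) + 1L)  # anti-diagonal counts
  comps <- matrix(0, n, r)
  for (i in seq_len(r)) {
    comps[, i] <- d[i] * hankel_antidiag_sums(sv$u[, i], sv$v[, i]) / w
  }
  labels <- group_components(comps, d[seq_len(r)], fs, trend_max_hz,
                             trend_energy_frac, pair_freq_tol)
  remainder <- x - rowSums(comps)
  scale <- max(abs(x), 1e-300)
  if (max(abs(remainder)) > 1e-10 * scale) {
    comps <- cbind(comps, remainder)
    labels <- c(labels, "residual")
  }
  dimnames(comps) <- NULL
  structure(
    list(signal = x, fs = fs, window_samples = L, components = comps,
         singular_values = d, grouping = labels, n_eigen = r),
    class = "ssa_decomposition"
  )
}

# anti-diagonal sums of outer(u, v): s[t] = sum_{i+j-1 = t} u[i] v[j],
# i.e. the full discrete convolution of u and v
hankel_antidiag_sums <- function(u, v) {
  convolve(u, rev(v), type = "open")
}

group_components <- function(comps, d, fs, trend_max_hz, trend_energy_frac,
                             pair_freq_tol) {
  r <- ncol(comps)
  n <- nrow(comps)
  low_frac <- numeric(r)
  dom_freq <- numeric(r)
  kmax <- floor(n / 2)
  freqs <- (0:kmax) * fs / n
  for (i in seq_len(r)) {
    p <- Mod(fft(comps[, i])[1:(kmax + 1L)])^2
    tot <- sum(p)
    if (tot <= 0) { low_frac[i] <- 1; dom_freq[i] <- 0; next }
    low_frac[i] <- sum(p[freqs < trend_max_hz]) / tot
    # dominant frequency over the strictly positive bins
    dom_freq[i] <- if (kmax >= 1L) freqs[1L + which.max(p[-1L])] else 0
  }
  labels <- rep("residual", r)
  # trend: slow components, by energy concentration below trend_max_hz or by
  # the dominant frequency itself (catches secondary trend eigentriples
  # ranked below the oscillatory pair)
  is_trend <- low_frac >= trend_energy_frac | dom_freq < trend_max_hz
  labels[is_trend] <- "trend"
  negligible <- d <= d[1L] * 1e-9
  cand <- which(labels != "trend" & !negligible & low_frac < trend_energy_frac)
  if (length(cand)) {
    best <- NULL
    best_energy <- -Inf
    if (length(cand) >= 2L) {
      for (a in seq_len(length(cand) - 1L)) {
        for (b in (a + 1L):length(cand)) {
          i1 <- cand[a]; i2 <- cand[b]
          f1 <- dom_freq[i1]; f2 <- dom_freq[i2]
          if (f1 <= 0 || f2 <= 0) next
          if (abs(f1 - f2) <= pair_freq_tol * max(f1, f2)) {
            e <- d[i1]^2 + d[i2]^2
            if (e > best_energy) { best_energy <- e; best <- c(i1, i2) }
          }
        }
      }
    }
    if (is.null(best)) {
      osc <- cand[dom_freq[cand] > 0]
      if (length(osc)) best <- osc[which.max(d[osc])]
    }
    if (!is.null(best)) labels[best] <- "dominant"
  }
  labels
}

#' @export
print.ssa_decomposition <- function(x, ...) {
  cat(sprintf("<ssa_decomposition> n = %d, L = %d, %d eigentriple(s)\n",
              length(x$signal), x$window_samples, x$n_eigen))
  cat("  grouping:", paste(sprintf("%s", x$grouping), collapse = " "), "\n")
  invisible(x)
}

#' Sum of a decomposition's component group
#'
#' @param dec an [ssa_decompose()] result.
#' @param group one of `"trend"`, `"dominant"`, `"residual"`.
#' @return numeric vector (zeros when the group is empty).
#' @export
ssa_group <- function(dec, group = c("trend", "dominant", "residual")) {
  group <- match.arg(group)
  sel <- dec$grouping == group
  if (!any(sel)) return(numeric(length(dec$signal)))
  rowSums(dec$components[, sel, drop = FALSE])
}

#' Dominant oscillation of a decomposed signal
#'
#' Returns the summed components labelled `dominant`: the non-trend harmonic
#' pair (or lone oscillatory component) with the largest singular-value
#' energy. For gait acceleration this is the fundamental stepping (SI) or
#' sway (ML) oscillation whose peaks and slopes the detectors read.
#'
#' @param dec an [ssa_decompose()] result.
#' @return numeric vector, same length as the input signal.
#' @export
dominant_oscillation <- function(dec) {
  if (!any(dec$grouping == "dominant")) {
    stop("flat signal: no oscillatory component found", call. = FALSE)
  }
  ssa_group(dec, "dominant")
}

#' Signal with its SSA trend removed
#'
#' @param dec an [ssa_decompose()] result.
#' @return the original signal minus the trend-group reconstruction.
#' @export
trend_removed <- function(dec) {
  dec$signal - ssa_group(dec, "trend")
}

#' Dump a decomposition to CSV (one component per column) for debugging
#'
#' @param dec an [ssa_decompose()] result.
#' @param path output path.
#' @export
write_ssa_components <- function(dec, path) {
  df <- as.data.frame(dec$components)
  names(df) <- sprintf("%s_%02d", dec$grouping, seq_along(dec$grouping))
  write.csv(cbind(signal = dec$signal, df), path, row.names = FALSE)
  invisible(path)
}
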