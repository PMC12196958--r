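#' Gait-event tables
#'
#' A gait-event table records detected or ground-truth events: `sample`
#' (0-based index into the trial, matching the `sample` column of trial
#' CSVs), `kind` (`"IC"` initial contact or `"TC"` terminal contact), `side`
#' (`"L"`, `"R"`, or `"U"` when laterality is unknown, as for detected TCs)
#' and `source` (`"diao"`, `"tpear"`, `"truth"`, ...). Rows are kept sorted
#' by `sample`.
#'
#' @param sample integer vector of 0-based sample indices.
#' @param kind character vector, `"IC"` or `"TC"`.
#' @param side character vector, `"L"`, `"R"` or `"U"`.
#' @param source single label for the stream.
#' @return a `data.frame` with class `gait_events`.
#' @export
gait_events <- function(sample = integer(0), kind = character(0),
                        side = character(0), source = "unknown") {
  kind <- as.character(kind)
  side <- as.character(side)
  if (!all(kind %in% c("IC", "TC"))) stop("kind must be IC or TC", call. = FALSE)
  if (!all(side %in% c("L", "R", "U"))) stop("side must be L, R or U", call. = FALSE)
  df <- data.frame(sample = as.integer(sample), kind = kind, side = side,
                   source = rep_len(as.character(source), length(sample)),
                   stringsAsFactors = FALSE)
  df <- df[order(df$sample, df$kind), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("gait_events", "data.frame")
  df
}

#' Step laterality from the dominant mediolateral oscillation
#'
#' During straight-line walking the head sways mediolaterally once per
#' stride, so the slope of the dominant ML oscillation at an initial contact
#' encodes which foot struck: with ML positive toward the left, the signed
#' difference between consecutive samples of the dominant ML series at the
#' IC is positive for a left IC and non-positive for a right IC.
#'
#' @param ml_dominant dominant ML oscillation (numeric vector).
#' @param ic_idx integer vector of IC positions as 1-based indices into
#'   `ml_dominant`.
#' @param invert flip the mapping for the opposite ML sign convention.
#' @return character vector of `"L"`/`"R"`, one per IC.
#' @export
determine_laterality <- function(ml_dominant, ic_idx, invert = FALSE) {
  n <- length(ml_dominant)
  vapply(as.integer(ic_idx), function(i) {
    if (i < 1L || i > n) stop("IC index out of bounds", call. = FALSE)
    d <- if (i == 1L) ml_dominant[2L] - ml_dominant[1L]
         else ml_dominant[i] - ml_dominant[i - 1L]
    left <- d > 0
    if (invert) left <- !left
    if (left) "L" else "R"
  }, character(1L))
}

#' Trusted-swing window around one dominant-SI peak
#'
#' For each peak of the dominant SI oscillation, TP-EAR inspects the raw
#' (band-passed) SI signal only inside a window that opens at the last point
#' before the peak where the dominant signal is at 80% of the peak amplitude
#' and closes at the next minimum of the dominant signal after the peak.
#'
#' @param dominant_si dominant SI oscillation (numeric vector).
#' @param peak_index 1-based index of a local maximum of `dominant_si`.
#' @param open_frac amplitude fraction at which the window opens (default 0.8).
#' @return list with `open`, `close`, `peak` (1-based indices,
#'   `open <= peak < close`) and `truncated` (TRUE when the window hit a
#'   series edge before the criterion was met).
#' @export
tpear_window <- function(dominant_si, peak_index, open_frac = 0.8) {
  n <- length(dominant_si)
  p <- as.integer(peak_index)
  if (p < 1L || p > n) stop("peak_index out of bounds", call. = FALSE)
  thr <- open_frac * dominant_si[p]
  truncated <- FALSE
  open <- p
  repeat {
    if (open == 1L) { truncated <- TRUE; break }
    if (dominant_si[open - 1L] <= thr) { open <- open - 1L; break }
    open <- open - 1L
  }
  mins <- local_minima(dominant_si)
  after <- mins[mins > p]
  if (length(after)) {
    close <- after[1L]
  } else {
    close <- n
    truncated <- TRUE
  }
  if (close <= p) { close <- min(p + 1L, n); truncated <- TRUE }
  list(open = open, close = close, peak = p, truncated = truncated)
}

# peaks of a smooth dominant oscillation: derivative zero crossings (strict
# local maxima), with a relative height gate against edge ripple
dominant_peaks <- function(dom, min_height_frac = 0.2) {
  n <- length(dom)
  if (n < 3L) return(integer(0))
  cand <- which(dom[2:(n - 1L)] > dom[1:(n - 2L)] & dom[2:(n - 1L)] > dom[3:n]) + 1L
  cand[dom[cand] > min_height_frac * max(dom)]
}

# shared guts: band-pass + SSA of the SI and ML channels
prep_channels <- function(trial, high_hz, low_hz = 0.5, order = 4L) {
  if (anyNA(trial$accel)) {
    stop("trial contains missing samples; run fill_gaps() first", call. = FALSE)
  }
  si_f <- bandpass(trial$accel[, "si"], low_hz, high_hz, trial$fs, order)
  ml_f <- bandpass(trial$accel[, "ml"], low_hz, high_hz, trial$fs, order)
  if (stats::sd(si_f) < 1e-9) {
    stop("flat signal: no gait oscillation present", call. = FALSE)
  }
  list(
    si_f = si_f, ml_f = ml_f,
    dec_si = ssa_decompose(si_f, trial$fs),
    dec_ml = ssa_decompose(ml_f, trial$fs)
  )
}

#' Baseline SSA gait-event detector (Diao/Seifer)
#'
#' Initial contacts are the peaks of the dominant oscillation extracted by
#' SSA from the (0.5-5 Hz band-passed) superior-inferior acceleration. Step
#' laterality comes from the slope of the dominant mediolateral oscillation
#' at each IC. The terminal contact paired with an IC is the next local
#' extremum of the trend-removed ML signal after the IC - a maximum after a
#' left IC, a minimum after a right IC (the polarity mapping follows the
#' ML-positive-left convention and can be inverted for the opposite
#' mounting). Because TC detection reads the ML channel, this detector
#' degrades when lateral head movements disrupt that channel.
#'
#' @param trial a gap-filled [imu_trial()].
#' @param high_hz upper band edge for pre-filtering (default 5).
#' @param order band-pass filter order (default 4).
#' @param invert_laterality flip the L/R mapping (and with it the TC
#'   extremum polarity), see [determine_laterality()].
#' @param peak_height_frac relative height gate for dominant-peak picking.
#' @return a [gait_events()] table with `source = "diao"`; detected TCs
#'   carry side `"U"`.
#' @export
detect_events_diao <- function(trial, high_hz = 5, order = 4L,
                               invert_laterality = FALSE,
                               peak_height_frac = 0.2) {
  ch <- prep_channels(trial, high_hz = high_hz, order = order)
  dom_si <- dominant_oscillation(ch$dec_si)
  dom_ml <- dominant_oscillation(ch$dec_ml)
  tr_ml <- trend_removed(ch$dec_ml)
  ics <- dominant_peaks(dom_si, peak_height_frac)
  if (!length(ics)) {
    return(gait_events(source = "diao"))
  }
  sides <- determine_laterality(dom_ml, ics, invert = invert_laterality)
  maxima <- find_peaks(tr_ml, prominence_frac = 0.05)
  minima <- find_peaks(-tr_ml, prominence_frac = 0.05)
  ev_sample <- integer(0); ev_kind <- character(0); ev_side <- character(0)
  next_ic <- c(ics[-1L], Inf)
  for (k in seq_along(ics)) {
    ev_sample <- c(ev_sample, ics[k]); ev_kind <- c(ev_kind, "IC")
    ev_side <- c(ev_side, sides[k])
    pool <- if (sides[k] == "L") maxima else minima
    tc <- pool[pool > ics[k] & pool < next_ic[k]]
    if (length(tc)) {
      ev_sample <- c(ev_sample, tc[1L]); ev_kind <- c(ev_kind, "TC")
      ev_side <- c(ev_side, "U")
    }
  }
  gait_events(sample = ev_sample - 1L, kind = ev_kind, side = ev_side,
              source = "diao")
}

#' TP-EAR gait-event detector
#'
#' TP-EAR derives both IC and TC from the superior-inferior acceleration,
#' which stays stable under lateral head movements. The SI channel is
#' band-pass filtered (0.5-12 Hz), SSA extracts its dominant oscillation,
#' and each dominant peak opens a trusted-swing window ([tpear_window()]).
#' The peaks of the filtered SI signal inside the window are counted:
#'
#' * 2 peaks: the first is the IC, the second the TC (the usual straight
#'   walking pattern);
#' * more than 2: the IC is the peak closest to the dominant peak (earlier
#'   peak on ties), the TC the latest peak with positive value;
#' * 1 peak: the segment is passed through [sharpen_peaks()] and re-counted;
#'   if still only one peak remains, the IC is the dominant peak itself and
#'   the TC the point of minimum gradient between the IC and the window end.
#'
#' Laterality is read from the dominant ML oscillation exactly as in
#' [detect_events_diao()]. A final ordering pass guarantees each emitted TC
#' lies strictly between its IC and the next IC.
#'
#' @inheritParams detect_events_diao
#' @param high_hz upper band edge for pre-filtering (default 12).
#' @param sharpen_weight weight passed to [sharpen_peaks()].
#' @return a [gait_events()] table with `source = "tpear"`.
#' @export
detect_events_tpear <- function(trial, high_hz = 12, order = 4L,
                                invert_laterality = FALSE,
                                peak_height_frac = 0.2, sharpen_weight = 1) {
  ch <- prep_channels(trial, high_hz = high_hz, order = order)
  f <- ch$si_f
  dom <- dominant_oscillation(ch$dec_si)
  dom_ml <- dominant_oscillation(ch$dec_ml)
  dpeaks <- dominant_peaks(dom, peak_height_frac)
  if (!length(dpeaks)) {
    return(gait_events(source = "tpear"))
  }
  # candidate raw-SI peaks with prominence measured on the whole series, so
  # that peaks sitting right at a window edge are not undervalued
  n <- length(f)
  all_pk <- which(f[2:(n - 1L)] > f[1:(n - 2L)] & f[2:(n - 1L)] > f[3:n]) + 1L
  all_prom <- vapply(all_pk, function(p) peak_prominence(f, p), numeric(1L))
  ic_idx <- integer(length(dpeaks))
  tc_idx <- rep(NA_integer_, length(dpeaks))
  for (k in seq_along(dpeaks)) {
    w <- tpear_window(dom, dpeaks[k])
    thr <- 0.05 * diff(range(f[w$open:w$close]))
    pk <- all_pk[all_pk >= w$open & all_pk <= w$close & all_prom >= thr]
    res <- tpear_branch(f, pk, w, dpeaks[k], sharpen_weight)
    ic_idx[k] <- res$ic
    tc_idx[k] <- res$tc
  }
  sides <- determine_laterality(dom_ml, ic_idx, invert = invert_laterality)
  ev_sample <- integer(0); ev_kind <- character(0); ev_side <- character(0)
  next_ic <- c(ic_idx[-1L], Inf)
  for (k in seq_along(ic_idx)) {
    ev_sample <- c(ev_sample, ic_idx[k]); ev_kind <- c(ev_kind, "IC")
    ev_side <- c(ev_side, sides[k])
    tc <- tc_idx[k]
    if (!is.na(tc) && tc > ic_idx[k] && tc < next_ic[k]) {
      ev_sample <- c(ev_sample, tc); ev_kind <- c(ev_kind, "TC")
      ev_side <- c(ev_side, "U")
    }
  }
  gait_events(sample = ev_sample - 1L, kind = ev_kind, side = ev_side,
              source = "tpear")
}

# the 1 / 2 / >2 peak-count branch rules of TP-EAR, on one window
tpear_branch <- function(f, pk, w, dpeak, sharpen_weight) {
  if (length(pk) == 2L) {
    return(list(ic = pk[1L], tc = pk[2L]))
  }
  if (length(pk) > 2L) {
    ic <- pk[which.min(abs(pk - dpeak))]        # ties resolve to earlier peak
    pos <- pk[f[pk] > 0]
    tc <- if (length(pos)) pos[length(pos)] else NA_integer_
    if (!is.na(tc) && tc > ic) return(list(ic = ic, tc = tc))
    return(min_gradient_fallback(f, ic, w$close))
  }
  # 0 or 1 peak: sharpen and re-count
  seg <- f[w$open:w$close]
  sharp <- sharpen_peaks(seg, weight = sharpen_weight)
  spk <- find_peaks(sharp, prominence_frac = 0.05) + w$open - 1L
  if (length(spk) >= 2L) {
    if (length(spk) == 2L) return(list(ic = spk[1L], tc = spk[2L]))
    ic <- spk[which.min(abs(spk - dpeak))]
    svals <- sharp[spk - w$open + 1L]
    pos <- spk[svals > 0]
    tc <- if (length(pos)) pos[length(pos)] else NA_integer_
    if (!is.na(tc) && tc > ic) return(list(ic = ic, tc = tc))
  }
  min_gradient_fallback(f, dpeak, w$close)
}

# IC at the dominant peak; TC at the minimum discrete gradient in (IC, close]
min_gradient_fallback <- function(f, ic, close) {
  if (close <= ic + 1L) return(list(ic = ic, tc = NA_integer_))
  g <- discrete_gradient(f[ic:close])
  rel <- which.min(g[-1L]) + 1L                 # exclude the IC sample itself
  list(ic = ic, tc = ic + rel - 1L)
}
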