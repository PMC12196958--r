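#' Enumerate dropped-sample gaps and apply the trial-exclusion rules
#'
#' Dropped packets leave runs of missing samples. A trial is excluded from
#' analysis when either (a) more than 10 consecutive samples are missing, or
#' (b) any gap lies within 0.3 s of a supplied reference initial contact,
#' since such a gap would directly interfere with detecting that event. Rule
#' (b) needs ground-truth ICs and is therefore only applied in evaluation
#' workflows where they are available.
#'
#' @param trial an [imu_trial()] with `missing_mask` populated.
#' @param reference_ics optional integer vector of ground-truth IC sample
#'   indices (0-based) used for the 0.3 s proximity rule.
#' @param max_consecutive longest tolerated missing run (default 10 samples).
#' @param ic_proximity_s half-width of the protected window around each
#'   reference IC, in seconds (default 0.3).
#' @return A `gap_report` list: `gaps` (data frame `start`, `length`, with
#'   0-based starts), `max_run`, `excluded`, and `exclusion_reason` (one of
#'   `"none"`, `"long_gap"`, `"gap_near_ic"`).
#' @export
detect_gaps <- function(trial, reference_ics = NULL, max_consecutive = 10L,
                        ic_proximity_s = 0.3) {
  mask <- trial$missing_mask
  gaps <- mask_runs(mask)
  max_run <- if (nrow(gaps)) max(gaps$length) else 0L
  excluded <- FALSE
  reason <- "none"
  if (max_run > max_consecutive) {
    excluded <- TRUE
    reason <- "long_gap"
  } else if (nrow(gaps) && length(reference_ics)) {
    win <- ic_proximity_s * trial$fs
    miss_idx <- which(mask) - 1L   # 0-based
    near <- vapply(as.numeric(reference_ics), function(ic) {
      any(abs(miss_idx - ic) <= win)
    }, logical(1L))
    if (any(near)) {
      excluded <- TRUE
      reason <- "gap_near_ic"
    }
  }
  structure(
    list(gaps = gaps, max_run = max_run, excluded = excluded,
         exclusion_reason = reason),
    class = "gap_report"
  )
}

# runs of TRUE in a logical mask -> data.frame(start (0-based), length)
mask_runs <- function(mask) {
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep] - 1L, length = r$lengths[keep])
}

#' @export
print.gap_report <- function(x, ...) {
  cat(sprintf("<gap_report> %d gap(s), longest run %d; excluded: %s (%s)\n",
              nrow(x$gaps), x$max_run, x$excluded, x$exclusion_reason))
  invisible(x)
}

#' Repair missing samples by cubic-spline interpolation
#'
#' Every sample flagged in `missing_mask` is replaced, channel by channel, by
#' a cubic spline fitted through the observed samples; observed samples are
#' left bit-identical. Missing runs at the very start or end of a trial have
#' no bracketing data, so they are filled by holding the nearest observed
#' value rather than extrapolating the cubic, and a warning is raised.
#'
#' @param trial an [imu_trial()]; should not be excluded per [detect_gaps()].
#' @return a repaired [imu_trial()]; `missing_mask` still records which
#'   samples were filled.
#' @export
fill_gaps <- function(trial) {
  mask <- trial$missing_mask
  if (!any(mask)) return(trial)
  obs <- which(!mask)
  if (length(obs) < 4L) {
    stop("need at least 4 observed samples per channel to spline-fill",
         call. = FALSE)
  }
  if (mask[1L] || mask[length(mask)]) {
    warning("missing samples at trial boundary filled by nearest-value hold")
  }
  fill_one <- function(y) {
    interior <- mask & seq_along(y) >= obs[1L] & seq_along(y) <= obs[length(obs)]
    if (any(interior)) {
      sf <- splinefun(obs, y[obs], method = "fmm")
      y[interior] <- sf(which(interior))
    }
    # boundary holds
    if (mask[1L]) y[seq_len(obs[1L] - 1L)] <- y[obs[1L]]
    last <- obs[length(obs)]
    if (mask[length(y)] && last < length(y)) {
      y[(last + 1L):length(y)] <- y[last]
    }
    y
  }
  for (j in seq_len(3L)) {
    trial$accel[, j] <- fill_one(trial$accel[, j])
    trial$gyro[, j] <- fill_one(trial$gyro[, j])
  }
  trial
}
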