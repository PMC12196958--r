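#' Align two recordings by maximizing cross-correlation
#'
#' When ground truth comes from a separately clocked system (e.g. an optical
#' motion capture trigger), small start-time differences are corrected by the
#' integer lag that maximizes the cross-correlation between a shared signal
#' recorded by both systems.
#'
#' @param imu_signal,reference_signal numeric vectors at the same sampling
#'   rate, after mean removal internally.
#' @param max_lag largest lag searched, in samples (default half the shorter
#'   series).
#' @return integer lag `k` such that `imu_signal[t]` best matches
#'   `reference_signal[t - k]`; positive means the IMU stream starts late.
#' @export
align_start <- function(imu_signal, reference_signal, max_lag = NULL) {
  x <- as.numeric(imu_signal); y <- as.numeric(reference_signal)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined lag: at least one series is flat", call. = FALSE)
  }
  x <- x - mean(x); y <- y - mean(y)
  if (is.null(max_lag)) max_lag <- floor(min(length(x), length(y)) / 2)
  lags <- -max_lag:max_lag
  cc <- vapply(lags, function(k) {
    # overlap of x[t] with y[t - k]
    t0 <- max(1L, 1L + k); t1 <- min(length(x), length(y) + k)
    if (t0 > t1) return(-Inf)
    sum(x[t0:t1] * y[(t0 - k):(t1 - k)])
  }, numeric(1L))
  lags[which.max(cc)]
}

#' Match detected events against ground truth within a tolerance window
#'
#' Events are compared per kind (ICs with ICs, TCs with TCs), ignoring side.
#' A detected event can match a ground-truth event only if their times differ
#' by at most `tolerance_s` (default 300 ms). Among all feasible one-to-one
#' assignments the matching maximizes the number of pairs and, among those,
#' minimizes the total absolute offset; because event times are ordered, an
#' optimal assignment is non-crossing and is found by dynamic programming.
#' Unmatched ground-truth events are false negatives, unmatched detected
#' events false positives.
#'
#' @param truth,detected [gait_events()] tables (sorted by sample).
#' @param tolerance_s matching tolerance in seconds (default 0.3).
#' @param fs sampling rate in Hz used to convert samples to seconds.
#' @return a `match_result` list: `pairs` (data frame `kind`, `truth_sample`,
#'   `det_sample`, `truth_side`, `det_side`, `offset_s` = detected - truth),
#'   `false_negatives`, `false_positives` (event subsets), `tolerance_s`.
#' @export
match_events <- function(truth, detected, tolerance_s = 0.3, fs = 100) {
  pairs <- list()
  fn <- list(); fp <- list()
  for (k in c("IC", "TC")) {
    tr <- truth[truth$kind == k, , drop = FALSE]
    de <- detected[detected$kind == k, , drop = FALSE]
    m <- match_sorted(tr$sample / fs, de$sample / fs, tolerance_s)
    if (length(m$ti)) {
      pairs[[k]] <- data.frame(
        kind = k,
        truth_sample = tr$sample[m$ti], det_sample = de$sample[m$di],
        truth_side = tr$side[m$ti], det_side = de$side[m$di],
        offset_s = (de$sample[m$di] - tr$sample[m$ti]) / fs,
        stringsAsFactors = FALSE
      )
    }
    fn[[k]] <- tr[setdiff(seq_len(nrow(tr)), m$ti), , drop = FALSE]
    fp[[k]] <- de[setdiff(seq_len(nrow(de)), m$di), , drop = FALSE]
  }
  pairs_df <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(kind = character(0), truth_sample = integer(0),
               det_sample = integer(0), truth_side = character(0),
               det_side = character(0), offset_s = numeric(0))
  rownames(pairs_df) <- NULL
  structure(
    list(pairs = pairs_df,
         false_negatives = do.call(rbind, fn),
         false_positives = do.call(rbind, fp),
         tolerance_s = tolerance_s),
    class = "match_result"
  )
}

# optimal non-crossing one-to-one matching of two sorted time vectors:
# lexicographically (max pairs, min total |offset|), offsets capped by tol
match_sorted <- function(t, d, tol) {
  n <- length(t); m <- length(d)
  if (n == 0L || m == 0L) return(list(ti = integer(0), di = integer(0)))
  npair <- matrix(0L, n + 1L, m + 1L)
  cost <- matrix(0, n + 1L, m + 1L)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      # skip truth i or detected j
      best_p <- npair[i, j + 1L]; best_c <- cost[i, j + 1L]; from <- 1L
      if (npair[i + 1L, j] > best_p ||
          (npair[i + 1L, j] == best_p && cost[i + 1L, j] < best_c)) {
        best_p <- npair[i + 1L, j]; best_c <- cost[i + 1L, j]; from <- 2L
      }
      off <- abs(t[i] - d[j])
      if (off <= tol) {
        p <- npair[i, j] + 1L; cc <- cost[i, j] + off
        if (p > best_p || (p == best_p && cc < best_c)) {
          best_p <- p; best_c <- cc; from <- 3L
        }
      }
      npair[i + 1L, j + 1L] <- best_p
      cost[i + 1L, j + 1L] <- best_c
    }
  }
  # backtrack
  ti <- integer(0); di <- integer(0)
  i <- n; j <- m
  while (i > 0L && j > 0L) {
    off <- abs(t[i] - d[j])
    if (off <= tol &&
        npair[i + 1L, j + 1L] == npair[i, j] + 1L &&
        abs(cost[i + 1L, j + 1L] - (cost[i, j] + off)) < 1e-12) {
      ti <- c(i, ti); di <- c(j, di); i <- i - 1L; j <- j - 1L
    } else if (npair[i + 1L, j + 1L] == npair[i, j + 1L] &&
               cost[i + 1L, j + 1L] == cost[i, j + 1L]) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  list(ti = ti, di = di)
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %d pair(s), %d FN, %d FP (tolerance %g s)\n",
              nrow(x$pairs), nrow(x$false_negatives), nrow(x$false_positives),
              x$tolerance_s))
  invisible(x)
}

#' Detection sensitivity of a matching
#'
#' `100 * pairs / (pairs + false negatives)`, optionally restricted to one
#' event kind. `NA` when there are no ground-truth events of that kind.
#'
#' @param match a [match_events()] result.
#' @param kind `"IC"`, `"TC"` or `NULL` for all events.
#' @return percentage in `[0, 100]`, or `NA`.
#' @export
sensitivity <- function(match, kind = NULL) {
  p <- match$pairs; fn <- match$false_negatives
  if (!is.null(kind)) {
    p <- p[p$kind == kind, , drop = FALSE]
    fn <- fn[fn$kind == kind, , drop = FALSE]
  }
  total <- nrow(p) + nrow(fn)
  if (total == 0L) return(NA_real_)
  100 * nrow(p) / total
}

#' Laterality accuracy over matched initial contacts
#'
#' Percentage of matched IC pairs whose detected side equals the
#' ground-truth side. Pairs whose side is unknown (`"U"`) on either stream
#' are excluded. `NA` when no eligible pairs exist.
#'
#' @param match a [match_events()] result.
#' @return percentage in `[0, 100]`, or `NA`.
#' @export
laterality_accuracy <- function(match) {
  p <- match$pairs
  p <- p[p$kind == "IC" & p$truth_side %in% c("L", "R") &
           p$det_side %in% c("L", "R"), , drop = FALSE]
  if (!nrow(p)) return(NA_real_)
  100 * mean(p$truth_side == p$det_side)
}

#' Temporal-parameter error statistics
#'
#' Pairs ground-truth cycles with detected cycles through the event matching
#' (a truth cycle pairs with the detected cycle whose bounding ICs are the
#' matched partners of the truth cycle's bounding ICs), then reports, for
#' stride, stance and swing time, the mean and standard deviation of the
#' absolute error (AE) and of the signed error (SE = detected - truth), in
#' milliseconds.
#'
#' @param truth_cycles,detected_cycles [build_cycles()] results.
#' @param match the [match_events()] result linking the two event streams.
#' @return data frame with one row per parameter: `param`, `n` (paired
#'   cycles), `mae_ms`, `sd_ae_ms`, `mse_ms`, `sd_se_ms`. Zero paired cycles
#'   yield `n = 0` and `NA` statistics.
#' @export
temporal_error_stats <- function(truth_cycles, detected_cycles, match) {
  icp <- match$pairs[match$pairs$kind == "IC", , drop = FALSE]
  map <- stats::setNames(icp$det_sample, icp$truth_sample)
  params <- c("stride_s", "stance_s", "swing_s")
  se <- list(stride_s = numeric(0), stance_s = numeric(0),
             swing_s = numeric(0))
  for (r in seq_len(nrow(truth_cycles))) {
    ds <- map[as.character(truth_cycles$ic_start[r])]
    de <- map[as.character(truth_cycles$ic_end[r])]
    if (is.na(ds) || is.na(de)) next
    hit <- which(detected_cycles$ic_start == ds & detected_cycles$ic_end == de)
    if (!length(hit)) next
    for (p in params) {
      se[[p]] <- c(se[[p]],
                   (detected_cycles[[p]][hit[1L]] - truth_cycles[[p]][r]) * 1000)
    }
  }
  out <- do.call(rbind, lapply(params, function(p) {
    e <- se[[p]]
    data.frame(param = sub("_s$", "", p), n = length(e),
               mae_ms = if (length(e)) mean(abs(e)) else NA_real_,
               sd_ae_ms = if (length(e) > 1L) stats::sd(abs(e)) else NA_real_,
               mse_ms = if (length(e)) mean(e) else NA_real_,
               sd_se_ms = if (length(e) > 1L) stats::sd(e) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
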