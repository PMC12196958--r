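#' Locate the single turn in a trial from the yaw track
#'
#' In a timed-up-and-go-style trial the participant performs exactly one
#' body turn. Because the head starts rotating before the body's centre of
#' mass, the turn start is declared at the earliest sample where the yaw
#' magnitude exceeds `start_yaw_deg` *and* the yaw rate magnitude exceeds
#' `start_rate_dps` (both conditions at the same sample); the turn ends at
#' the earliest subsequent sample where the yaw magnitude reaches its
#' trial-wide maximum minus `end_margin_deg` - the point at which the head
#' has essentially completed its rotation. The angle offsets suppress false
#' starts from incidental head movements.
#'
#' @param yaw yaw series in degrees, referenced to the pre-turn heading
#'   (zero at trial start) and unwrapped.
#' @param rate yaw-rate series in deg/s (e.g. [yaw_rate()]); same length as
#'   `yaw`.
#' @param start_yaw_deg yaw threshold for the start criterion (default 15).
#' @param start_rate_dps yaw-rate threshold for the start criterion
#'   (default 30).
#' @param end_margin_deg margin below the yaw maximum for the end criterion
#'   (default 5).
#' @return a `turn_interval` list: `start_index`, `end_index` (1-based
#'   samples), `yaw_max_abs` (degrees) and the thresholds used - or `NULL`
#'   (a no-turn result) when no sample satisfies the start criterion or the
#'   yaw excursion never exceeds `start_yaw_deg`.
#' @export
segment_turn <- function(yaw, rate, start_yaw_deg = 15, start_rate_dps = 30,
                         end_margin_deg = 5) {
  yaw <- as.numeric(yaw); rate <- as.numeric(rate)
  if (length(yaw) != length(rate)) {
    stop("yaw and rate must have the same length", call. = FALSE)
  }
  yaw_max_abs <- max(abs(yaw))
  if (yaw_max_abs <= start_yaw_deg) return(NULL)
  hits <- which(abs(yaw) > start_yaw_deg & abs(rate) > start_rate_dps)
  if (!length(hits)) return(NULL)
  start <- hits[1L]
  ends <- which(abs(yaw) >= yaw_max_abs - end_margin_deg)
  ends <- ends[ends >= start]
  if (!length(ends)) return(NULL)   # unreachable: the max itself qualifies
  end <- ends[1L]
  if (end == start) end <- min(end + 1L, length(yaw))
  out <- structure(
    list(start_index = start, end_index = end, yaw_max_abs = yaw_max_abs,
         start_yaw_deg = start_yaw_deg, start_rate_dps = start_rate_dps,
         end_margin_deg = end_margin_deg),
    class = "turn_interval"
  )
  stopifnot(out$start_index < out$end_index,
            abs(yaw[out$start_index]) > start_yaw_deg,
            abs(yaw[out$end_index]) >= yaw_max_abs - end_margin_deg)
  out
}

#' @export
print.turn_interval <- function(x, ...) {
  cat(sprintf("<turn_interval> samples %d..%d, |yaw|max = %.1f deg\n",
              x$start_index, x$end_index, x$yaw_max_abs))
  invisible(x)
}

#' Split an event stream by a turn interval
#'
#' @param events a [gait_events()] table.
#' @param interval a [segment_turn()] result (1-based indices).
#' @return list of event tables `pre`, `turn`, `post`.
#' @export
split_events_by_turn <- function(events, interval) {
  s0 <- interval$start_index - 1L   # events are 0-based
  s1 <- interval$end_index - 1L
  list(
    pre = events[events$sample < s0, , drop = FALSE],
    turn = events[events$sample >= s0 & events$sample <= s1, , drop = FALSE],
    post = events[events$sample > s1, , drop = FALSE]
  )
}
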