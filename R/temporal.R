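#' Per-cycle stride, stance and swing times from an event stream
#'
#' A gait cycle runs between consecutive initial contacts of the same foot.
#' For each pair of consecutive same-side ICs the durations are
#'
#' * stride = (IC_end - IC_start) / fs
#' * stance = (TC - IC_start) / fs
#' * swing  = (IC_end - TC) / fs
#'
#' so stride = stance + swing holds exactly by construction. The TC
#' attributed to a cycle is the first TC of the same stream falling strictly
#' between the two ICs; detected TC events carry no laterality, so no side
#' constraint is imposed (when both feet's TCs are present in the stream the
#' first in-span TC is the contralateral foot-off, and the `stance` column
#' measures the IC-to-first-TC interval; see the package vignette). Cycles
#' with no in-span TC are skipped.
#'
#' @param events a [gait_events()] table with sides assigned to ICs.
#' @param fs sampling rate in Hz.
#' @return data frame of class `cycle_params` with columns `side`,
#'   `ic_start`, `tc`, `ic_end` (0-based samples) and `stride_s`, `stance_s`,
#'   `swing_s` (seconds).
#' @export
build_cycles <- function(events, fs) {
  stopifnot(is.data.frame(events))
  if (is.unsorted(events$sample)) {
    stop("events must be sorted by sample", call. = FALSE)
  }
  tcs <- events$sample[events$kind == "TC"]
  rows <- list()
  for (s in c("L", "R")) {
    ics <- events$sample[events$kind == "IC" & events$side == s]
    if (length(ics) < 2L) next
    for (k in seq_len(length(ics) - 1L)) {
      ic0 <- ics[k]; ic1 <- ics[k + 1L]
      inspan <- tcs[tcs > ic0 & tcs < ic1]
      if (!length(inspan)) next
      if (length(inspan) > 2L) {
        warning(sprintf("%d TCs between ICs at %d and %d; using the first",
                        length(inspan), ic0, ic1))
      }
      tc <- inspan[1L]
      stance <- (tc - ic0) / fs
      swing <- (ic1 - tc) / fs
      rows[[length(rows) + 1L]] <- data.frame(
        side = s, ic_start = ic0, tc = tc, ic_end = ic1,
        stride_s = stance + swing,   # the identity holds to the last bit
        stance_s = stance,
        swing_s = swing,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(side = character(0), ic_start = integer(0), tc = integer(0),
               ic_end = integer(0), stride_s = numeric(0),
               stance_s = numeric(0), swing_s = numeric(0))
  out <- out[order(out$ic_start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cycle_params", "data.frame")
  out
}
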