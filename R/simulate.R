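#' Configuration for the synthetic gait-trial simulator
#'
#' The simulator emulates four standard clinical walking-task families: straight
#' walking (`head_turn = "none"`, no `turn`), walking with vertical or
#' horizontal head turns, and a timed-up-and-go-style trial with a single
#' body turn. Signal morphology follows what an ear-worn IMU records: the
#' superior-inferior (SI) acceleration carries two impact transients per
#' step - a larger one at initial contact and a smaller one at the following
#' terminal contact (a foot-off push is visible as an SI peak at the head) -
#' while the mediolateral (ML) acceleration sways once per stride, its slope
#' at each IC encoding the stepping side (rising = left under the
#' ML-positive-left convention). Head-turn perturbations are additive
#' sinusoids at the instructed ~2 Hz rate: on ML (plus a yaw gyro
#' oscillation) for horizontal turns, on SI (plus a pitch gyro oscillation)
#' for vertical turns - reproducing the failure mode that motivates TP-EAR:
#' horizontal head turns disrupt ML but leave the SI event template
#' unchanged.
#'
#' @param n_cycles gait cycles per side (steps = `2 * n_cycles`); >= 2.
#' @param stride_s stride duration, s (default 1.1).
#' @param stance_fraction fraction of the stride a foot is on the ground
#'   (default 0.6; must be in (0, 1), and with both feet's TCs in the stream
#'   values > 0.5 put one contralateral TC between successive ICs, as in
#'   normal double-support walking).
#' @param si_peak_amp IC transient amplitude on SI, m/s^2 (default 2).
#' @param tc_amp_frac TC transient amplitude relative to IC (default 0.6).
#' @param bump_width_s Gaussian transient width (sigma), s (default 0.030).
#' @param ml_amp ML sway amplitude, m/s^2 (default 0.8).
#' @param ap_amp AP oscillation amplitude, m/s^2 (default 0.3).
#' @param noise_sd white accelerometer noise, m/s^2 (default 0.05).
#' @param gyro_noise_dps white gyro noise, deg/s (default 0.2).
#' @param head_turn `"none"`, `"vertical"` or `"horizontal"`.
#' @param head_turn_rate_hz head-turn rate (default 2, the instructed rate).
#' @param head_turn_amp amplitude of the acceleration perturbation, m/s^2
#'   (default 0.4).
#' @param head_turn_yaw_deg head-yaw oscillation amplitude for horizontal
#'   turns, degrees (default 10).
#' @param turn optional body turn: list `onset_s`, `duration_s`,
#'   `total_yaw_deg` (smoothstep yaw profile).
#' @param turn_ml_coupling ML disturbance per deg/s of body-turn yaw rate,
#'   m/s^2 (default 0.004).
#' @param dropped_samples optional list of `c(start, length)` 0-based gaps
#'   applied through [inject_gaps()].
#' @param pad_s quiet standing before the first and after the last step, s
#'   (default 1).
#' @param fs sampling rate, Hz (default 100).
#' @param seed RNG seed; the same seed reproduces the trial bit-for-bit.
#' @return a `gait_sim_config` list.
#' @export
gait_sim_config <- function(n_cycles = 10L, stride_s = 1.1,
                            stance_fraction = 0.6, si_peak_amp = 2,
                            tc_amp_frac = 0.6, bump_width_s = 0.030,
                            ml_amp = 0.8, ap_amp = 0.3, noise_sd = 0.05,
                            gyro_noise_dps = 0.2,
                            head_turn = c("none", "vertical", "horizontal"),
                            head_turn_rate_hz = 2, head_turn_amp = 0.4,
                            head_turn_yaw_deg = 10, turn = NULL,
                            turn_ml_coupling = 0.004, dropped_samples = NULL,
                            pad_s = 1, fs = 100, seed = 1L) {
  head_turn <- match.arg(head_turn)
  if (n_cycles < 2L) stop("n_cycles must be >= 2", call. = FALSE)
  if (stance_fraction <= 0 || stance_fraction >= 1) {
    stop("stance_fraction must be in (0, 1)", call. = FALSE)
  }
  if (!is.null(turn)) {
    stopifnot(all(c("onset_s", "duration_s", "total_yaw_deg") %in% names(turn)))
  }
  cfg <- as.list(environment())
  class(cfg) <- "gait_sim_config"
  cfg
}

gaussian_bumps <- function(t, centers, amp, sigma) {
  out <- numeric(length(t))
  for (c0 in centers) {
    out <- out + amp * exp(-((t - c0)^2) / (2 * sigma^2))
  }
  out
}

smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  3 * u^2 - 2 * u^3
}

#' Simulate one ear-worn IMU gait trial with known ground truth
#'
#' @param config a [gait_sim_config()].
#' @return list with `trial` (an [imu_trial()]) and `truth`, a `sim_truth`
#'   list holding `events` (a [gait_events()] table, `source = "truth"`, TC
#'   sides = the foot that lifted), `cycles` (truth [build_cycles()] output),
#'   `yaw`/`yaw_rate` (the programmed head-yaw track, degrees and deg/s),
#'   `turn_interval` (1-based start/end of the body turn per the yaw
#'   criteria, or `NULL`) and the generating `config`.
#' @export
simulate_trial <- function(config) {
  stopifnot(inherits(config, "gait_sim_config"))
  cfg <- config
  fs <- cfg$fs
  duration <- 2 * cfg$pad_s + cfg$n_cycles * cfg$stride_s
  n <- as.integer(round(duration * fs))
  t <- (seq_len(n) - 1L) / fs

  t0 <- cfg$pad_s
  ic_l <- t0 + (seq_len(cfg$n_cycles) - 1L) * cfg$stride_s
  ic_r <- ic_l + cfg$stride_s / 2
  ics <- sort(c(ic_l, ic_r))
  tc_l <- ic_l + cfg$stance_fraction * cfg$stride_s
  tc_r <- ic_r + cfg$stance_fraction * cfg$stride_s
  # The trial emulates a walking bout trimmed to its steps, as laboratory trials
  # are: with stance_fraction > 0.5 (double-support walking) the recording
  # opens mid-swing - the foot that started before the recording lifts off
  # shortly after the first IC - and closes while the last stance foot is
  # still on the ground, so its foot-off is never recorded.
  tc_sides <- rep(c("L", "R"), each = cfg$n_cycles)
  if (cfg$stance_fraction > 0.5) {
    lead_tc <- t0 + (cfg$stance_fraction - 0.5) * cfg$stride_s
    last <- which.max(c(tc_l, tc_r))
    tcs <- c(lead_tc, c(tc_l, tc_r)[-last])
    tc_sides <- c("R", tc_sides[-last])
  } else {
    tcs <- c(tc_l, tc_r)
  }
  if (max(tcs) >= duration) {
    stop("trial too short for the configured stance; increase pad_s",
         call. = FALSE)
  }
  if (!is.null(cfg$turn) &&
      cfg$turn$onset_s + cfg$turn$duration_s > duration) {
    stop("configured turn extends beyond the trial", call. = FALSE)
  }

  set.seed(cfg$seed)
  noise_si <- rnorm(n, 0, cfg$noise_sd)
  noise_ml <- rnorm(n, 0, cfg$noise_sd)
  noise_ap <- rnorm(n, 0, cfg$noise_sd)
  gnoise <- matrix(rnorm(3L * n, 0, cfg$gyro_noise_dps), n, 3L)

  step_f <- 2 / cfg$stride_s
  si <- .GRAVITY +
    gaussian_bumps(t, ics, cfg$si_peak_amp, cfg$bump_width_s) +
    gaussian_bumps(t, tcs, cfg$si_peak_amp * cfg$tc_amp_frac,
                   cfg$bump_width_s)

  # ML sway: one period per stride, phased so that (a) the slope at each IC
  # encodes the side and (b) the first correct-polarity extremum after an IC
  # coincides with the first TC following it - the pattern the baseline
  # detector's TC rule assumes.
  all_tcs <- sort(tcs)
  delta <- min(all_tcs[all_tcs > ic_l[2L]]) - ic_l[2L]
  ml <- cfg$ml_amp *
    sin(2 * pi * (t - ic_l[1L] - delta + cfg$stride_s / 4) / cfg$stride_s)
  ap <- cfg$ap_amp * sin(2 * pi * step_f * (t - t0))

  gyro_si <- numeric(n)   # analysis frame; down rate = -gyro_si
  gyro_ml <- 3 * sin(2 * pi * step_f * (t - t0))        # gentle pitch nodding
  gyro_ap <- 2 * sin(2 * pi * (t - t0) / cfg$stride_s)  # gentle roll sway

  head_yaw <- numeric(n)
  if (cfg$head_turn == "horizontal") {
    w <- 2 * pi * cfg$head_turn_rate_hz
    ml <- ml + cfg$head_turn_amp * sin(w * (t - t0))
    head_yaw <- head_yaw + cfg$head_turn_yaw_deg * sin(w * (t - t0))
    gyro_si <- gyro_si - cfg$head_turn_yaw_deg * w * cos(w * (t - t0))
  } else if (cfg$head_turn == "vertical") {
    w <- 2 * pi * cfg$head_turn_rate_hz
    si <- si + cfg$head_turn_amp * sin(w * (t - t0))
    gyro_ml <- gyro_ml + cfg$head_turn_yaw_deg * w * cos(w * (t - t0))
  }

  body_yaw <- numeric(n)
  body_yaw_rate <- numeric(n)
  if (!is.null(cfg$turn)) {
    u <- (t - cfg$turn$onset_s) / cfg$turn$duration_s
    body_yaw <- cfg$turn$total_yaw_deg * smoothstep(u)
    du <- ifelse(u > 0 & u < 1, 6 * u * (1 - u), 0)
    body_yaw_rate <- cfg$turn$total_yaw_deg * du / cfg$turn$duration_s
    gyro_si <- gyro_si - body_yaw_rate
    ml <- ml + cfg$turn_ml_coupling * body_yaw_rate
  }

  trial <- imu_trial(
    accel = cbind(si = si + noise_si, ml = ml + noise_ml, ap = ap + noise_ap),
    gyro = cbind(si = gyro_si + gnoise[, 1L], ml = gyro_ml + gnoise[, 2L],
                 ap = gyro_ap + gnoise[, 3L]),
    fs = fs, side = "left",
    missing_mask = rep(FALSE, n)
  )

  ev_t <- c(ic_l, ic_r, tcs)
  ev_kind <- c(rep("IC", 2L * cfg$n_cycles), rep("TC", length(tcs)))
  ev_side <- c(rep(c("L", "R"), each = cfg$n_cycles), tc_sides)
  events <- gait_events(sample = round(ev_t * fs), kind = ev_kind,
                        side = ev_side, source = "truth")

  turn_interval <- NULL
  if (!is.null(cfg$turn)) {
    hit <- which(abs(body_yaw) > 15 & abs(body_yaw_rate) > 30)
    if (length(hit)) {
      start <- hit[1L]
      emax <- max(abs(body_yaw))
      ends <- which(abs(body_yaw) >= emax - 5)
      ends <- ends[ends >= start]
      turn_interval <- structure(
        list(start_index = start, end_index = ends[1L], yaw_max_abs = emax,
             start_yaw_deg = 15, start_rate_dps = 30, end_margin_deg = 5),
        class = "turn_interval"
      )
    }
  }

  truth <- structure(
    list(events = events, cycles = build_cycles(events, fs),
         yaw = body_yaw + head_yaw,
         yaw_rate = body_yaw_rate +
           if (cfg$head_turn == "horizontal")
             discrete_gradient(head_yaw, 1 / fs) else 0,
         turn_interval = turn_interval, config = cfg),
    class = "sim_truth"
  )

  if (!is.null(cfg$dropped_samples)) {
    trial <- inject_gaps(trial, cfg$dropped_samples)
  }
  list(trial = trial, truth = truth)
}

#' Mark dropped-sample gaps in a trial
#'
#' Emulates lost transmission packets: the listed samples are replaced by
#' `NA` and flagged in `missing_mask`; all other samples are untouched.
#' Overlapping gaps are merged with a warning.
#'
#' @param trial an [imu_trial()].
#' @param gaps list of `c(start, length)` pairs, starts 0-based.
#' @return the trial with gaps applied.
#' @export
inject_gaps <- function(trial, gaps) {
  if (!length(gaps)) return(trial)
  if (!is.list(gaps)) gaps <- list(gaps)
  idx <- integer(0)
  for (g in gaps) {
    if (length(g) != 2L) stop("each gap must be c(start, length)", call. = FALSE)
    s <- as.integer(g[1L]); len <- as.integer(g[2L])
    if (s < 0L || s + len > trial$n) stop("gap out of bounds", call. = FALSE)
    idx <- c(idx, seq.int(s + 1L, length.out = len))
  }
  if (anyDuplicated(idx)) {
    warning("overlapping gaps merged")
    idx <- unique(idx)
  }
  trial$accel[idx, ] <- NA_real_
  trial$gyro[idx, ] <- NA_real_
  trial$missing_mask[idx] <- TRUE
  trial
}
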