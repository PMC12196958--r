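test_that("band-pass keeps the passband, rejects drift and high frequency", {
  fs <- 100
  t <- (0:1999) / fs
  s2 <- sin(2 * pi * 2 * t)
  drift <- 3 * sin(2 * pi * 0.05 * t)
  out <- bandpass(drift + s2, 0.5, 12, fs)
  expect_gt(cor(out, s2), 0.99)
  s20 <- sin(2 * pi * 20 * t)
  expect_lt(sqrt(mean(bandpass(s20, 0.5, 12, fs)^2)) / sqrt(mean(s20^2)), 0.1)
  expect_equal(bandpass(rep(0, 500), 0.5, 12, fs), rep(0, 500))
  expect_error(bandpass(s2, 12, 0.5, fs), "low_hz < high_hz")
  expect_error(bandpass(s2, 0.5, 60, fs), "high_hz < fs/2")
})

test_that("laterality follows the sign of the dominant ML slope", {
  ml <- c(0, 0.3, 0.6, 0.3, 0)        # rising then falling
  expect_equal(determine_laterality(ml, 3), "L")   # diff +0.3
  expect_equal(determine_laterality(ml, 5), "R")   # diff -0.3
  expect_equal(determine_laterality(c(1, 1, 1), 2), "R")  # zero diff -> "otherwise"
  # IC at the first sample uses the forward difference
  expect_equal(determine_laterality(c(0, 1, 2), 1), "L")
  expect_equal(determine_laterality(ml, c(3, 5), invert = TRUE), c("R", "L"))
  expect_error(determine_laterality(ml, 9), "out of bounds")
})

test_that("trusted-swing windows open at the 80 % crossing and close at the minimum", {
  # triangle: rise 0 -> 1 over 50 samples, fall back over 50, then a short
  # rise so the base is an interior minimum
  tri <- c(seq(0, 1, length.out = 51), seq(1, 0, length.out = 51)[-1],
           c(0.05, 0.1))
  w <- tpear_window(tri, 51)
  expect_equal(w$open, 41)            # 0.8 crossing, 10 samples before apex
  expect_equal(w$close, 101)          # base minimum
  expect_false(w$truncated)

  # sine: open at the analytic 80 % amplitude crossing, close at next trough
  fs <- 100
  t <- (0:599) / fs
  dom <- sin(2 * pi * 1 * t)
  pk <- 26                            # apex of the first period (t = 0.25)
  w2 <- tpear_window(dom, pk)
  t_cross <- (pi / 2 - asin(0.8)) / (2 * pi)  # s before apex
  expect_lte(abs(w2$open - (pk - t_cross * fs)), 1.5)
  expect_equal(w2$close, 76)          # trough at t = 0.75
  # a peak with no earlier 0.8 crossing: open clamps to 1 and is flagged
  w3 <- tpear_window(c(0.95, 1, 0.5, 0.2, 0.4), 2)
  expect_equal(w3$open, 1)
  expect_true(w3$truncated)
})

test_that("peak sharpening preserves clear peaks and uncovers shoulders", {
  i <- 1:100
  g <- function(c0, a, s) a * exp(-((i - c0)^2) / (2 * s^2))
  # two well-separated peaks: count and locations unchanged (+/- 1 sample)
  x <- g(30, 1, 5) + g(70, 0.8, 5)
  p <- find_peaks(sharpen_peaks(x), prominence_frac = 0.05)
  expect_length(p, 2)
  expect_lte(max(abs(p - c(30, 70))), 1)
  # single peak stays single, in place
  p1 <- find_peaks(sharpen_peaks(g(50, 1, 5)), prominence_frac = 0.05)
  expect_length(p1, 1)
  expect_lte(abs(p1 - 50), 1)
  # 30 % shoulder at gait-transient scale becomes countable
  xs <- g(50, 1, 3) + g(58, 0.3, 3)
  expect_length(find_peaks(xs, prominence_frac = 0.05), 1)
  ps <- find_peaks(sharpen_peaks(xs), prominence_frac = 0.05)
  expect_length(ps, 2)
  expect_lte(abs(ps[1] - 50), 1)
  # deterministic
  expect_identical(sharpen_peaks(xs), sharpen_peaks(xs))
})

test_that("the more-than-two-peak branch picks closest-to-dominant IC and last positive TC", {
  f <- numeric(120)
  f[45] <- 1.2; f[52] <- 1.5; f[70] <- 0.8   # isolated spikes are peaks
  f[100] <- -0.5
  w <- list(open = 40L, close = 110L, peak = 50L, truncated = FALSE)
  res <- tpear:::tpear_branch(f, pk = c(45L, 52L, 70L), w = w, dpeak = 50L,
                              sharpen_weight = 1)
  expect_equal(res$ic, 52L)   # closest to the dominant peak at 50
  expect_equal(res$tc, 70L)   # latest peak with positive value
})

test_that("the single-peak fallback equals a brute-force gradient argmin", {
  set.seed(21)
  for (rep in 1:20) {
    f <- cumsum(rnorm(200))
    ic <- sample(50:100, 1)
    close <- ic + sample(20:60, 1)
    res <- tpear:::min_gradient_fallback(f, ic, close)
    # oracle: explicit loop over the central-difference gradient
    seg <- f[ic:close]
    g <- numeric(length(seg))
    for (k in seq_along(seg)) {
      g[k] <- if (k == 1) seg[2] - seg[1]
      else if (k == length(seg)) seg[k] - seg[k - 1]
      else (seg[k + 1] - seg[k - 1]) / 2
    }
    best <- which.min(g[-1]) + 1L
    expect_equal(res$tc, ic + best - 1L)
  }
})

test_that("both detectors recover noiseless simulated gait exactly enough", {
  sim <- simulate_trial(gait_sim_config(n_cycles = 20, noise_sd = 0,
                                        gyro_noise_dps = 0, seed = 3))
  truth <- sim$truth$events
  det_t <- detect_events_tpear(sim$trial)
  m_t <- match_events(truth, det_t)
  expect_gte(sensitivity(m_t, "IC"), 99)
  expect_gte(sensitivity(m_t, "TC"), 99)
  expect_equal(laterality_accuracy(m_t), 100)
  # TP-EAR events sit within +/- 2 samples of the programmed transients
  expect_lte(max(abs(m_t$pairs$offset_s)) * sim$trial$fs, 2)

  det_d <- detect_events_diao(sim$trial)
  m_d <- match_events(truth, det_d)
  expect_equal(sum(det_d$kind == "IC" &
                     det_d$sample >= min(truth$sample) - 30 &
                     det_d$sample <= max(truth$sample) + 30), 40)
  expect_gte(sensitivity(m_d, "IC"), 99)
  expect_equal(laterality_accuracy(m_d), 100)
})

test_that("a constant-acceleration trial raises the flat-signal error", {
  tr <- make_trial(si = rep(9.80665, 800))
  expect_error(detect_events_diao(tr), "flat signal")
  expect_error(detect_events_tpear(tr), "flat signal")
})

test_that("detectors are deterministic and emit well-ordered streams", {
  sim <- simulate_trial(gait_sim_config(n_cycles = 8, noise_sd = 0.1, seed = 4))
  a <- detect_events_tpear(sim$trial)
  b <- detect_events_tpear(sim$trial)
  expect_identical(a, b)
  for (det in list(a, detect_events_diao(sim$trial))) {
    expect_false(is.unsorted(det$sample))
    ics <- det$sample[det$kind == "IC"]
    for (tc in det$sample[det$kind == "TC"]) {
      prev_ic <- max(ics[ics < tc])
      next_ic <- suppressWarnings(min(ics[ics > tc]))
      expect_gt(tc, prev_ic)
      expect_lt(tc, next_ic)   # strict: at most one TC between ICs
    }
  }
})

test_that("IC sensitivity stays at ceiling under moderate noise across seeds", {
  for (seed in 1:30) {
    sim <- simulate_trial(gait_sim_config(n_cycles = 10, noise_sd = 0.1,
                                          seed = 100 + seed))
    truth <- sim$truth$events
    for (det in list(detect_events_diao(sim$trial),
                     detect_events_tpear(sim$trial))) {
      m <- match_events(truth, det)
      expect_gte(sensitivity(m, "IC"), 99)
    }
    # matched ICs alternate sides on clean simulator phase
    det <- detect_events_tpear(sim$trial)
    m <- match_events(truth, det)
    icp <- m$pairs[m$pairs$kind == "IC", ]
    sides <- icp$det_side[order(icp$det_sample)]
    expect_true(all(sides[-1] != sides[-length(sides)]))
  }
})

test_that("horizontal head turns leave TP-EAR TC sensitivity intact", {
  tc0 <- tc1 <- numeric(0)
  for (seed in 1:10) {
    base <- gait_sim_config(n_cycles = 10, noise_sd = 0.1, seed = 200 + seed)
    pert <- gait_sim_config(n_cycles = 10, noise_sd = 0.1,
                            head_turn = "horizontal", seed = 200 + seed)
    s0 <- simulate_trial(base); s1 <- simulate_trial(pert)
    # the premise: SI untouched, ML visibly disrupted
    expect_identical(s0$trial$accel[, "si"], s1$trial$accel[, "si"])
    expect_gt(sqrt(mean((s0$trial$accel[, "ml"] - s1$trial$accel[, "ml"])^2)), 0)
    m0 <- match_events(s0$truth$events, detect_events_tpear(s0$trial))
    m1 <- match_events(s1$truth$events, detect_events_tpear(s1$trial))
    tc0 <- c(tc0, sensitivity(m0, "TC")); tc1 <- c(tc1, sensitivity(m1, "TC"))
  }
  expect_gte(mean(tc1), mean(tc0) - 1)
})
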