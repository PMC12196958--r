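test_that("cross-correlation start alignment recovers integer lags", {
  set.seed(2)
  y <- sin(2 * pi * 1.3 * (0:999) / 100) + 0.2 * rnorm(1000)
  x <- c(rep(0, 17), y)[1:1000]          # x starts 17 samples late
  expect_equal(align_start(x, y), 17)
  expect_equal(align_start(y, y), 0)
  expect_error(align_start(rep(1, 100), y), "flat")
  for (seed in 1:20) {
    set.seed(seed)
    lag <- sample(5:60, 1)
    ref <- sin(2 * pi * 1.1 * (0:799) / 100)
    imu <- c(rep(0, lag), ref)[1:800] + rnorm(800, 0, 0.3)
    expect_lte(abs(align_start(imu, ref) - lag), 1)
  }
})

test_that("events match within 300 ms and split into FN/FP beyond it", {
  truth <- gait_events(sample = 500, kind = "IC", side = "L", source = "truth")
  det_near <- gait_events(sample = 525, kind = "IC", side = "L", source = "x")
  m <- match_events(truth, det_near, tolerance_s = 0.3, fs = 100)
  expect_equal(nrow(m$pairs), 1L)
  expect_equal(m$pairs$offset_s, 0.25)
  det_far <- gait_events(sample = 535, kind = "IC", side = "L", source = "x")
  m2 <- match_events(truth, det_far, tolerance_s = 0.3, fs = 100)
  expect_equal(nrow(m2$pairs), 0L)
  expect_equal(nrow(m2$false_negatives), 1L)
  expect_equal(nrow(m2$false_positives), 1L)
  # kinds never cross-match
  det_tc <- gait_events(sample = 500, kind = "TC", side = "U", source = "x")
  expect_equal(nrow(match_events(truth, det_tc)$pairs), 0L)
})

test_that("assignment equals exhaustive enumeration on random instances", {
  set.seed(13)
  for (rep in 1:25) {
    nt <- sample(1:8, 1); nd <- sample(1:8, 1)
    t <- sort(runif(nt, 0, 8))
    d <- sort(runif(nd, 0, 8))
    m <- match_events(
      gait_events(sample = round(t * 100), kind = "IC", side = "U", source = "t"),
      gait_events(sample = round(d * 100), kind = "IC", side = "U", source = "d"),
      tolerance_s = 0.3, fs = 100)
    ora <- brute_match(round(t * 100) / 100, round(d * 100) / 100, 0.3)
    expect_equal(nrow(m$pairs), ora$pairs)
    expect_equal(sum(abs(m$pairs$offset_s)), ora$cost, tolerance = 1e-9)
  }
})

test_that("matching is symmetric up to relabelling FN and FP", {
  set.seed(31)
  t <- gait_events(sample = sort(sample(0:2000, 12)), kind = "IC",
                   side = "U", source = "a")
  d <- gait_events(sample = sort(sample(0:2000, 10)), kind = "IC",
                   side = "U", source = "b")
  m1 <- match_events(t, d); m2 <- match_events(d, t)
  expect_equal(nrow(m1$pairs), nrow(m2$pairs))
  expect_equal(sort(m1$pairs$truth_sample), sort(m2$pairs$det_sample))
  expect_equal(nrow(m1$false_negatives), nrow(m2$false_positives))
  expect_equal(nrow(m1$false_positives), nrow(m2$false_negatives))
})

test_that("sensitivity and laterality accuracy are simple matched fractions", {
  # 99 matched + 1 missed = 99 %
  truth <- gait_events(sample = seq(0, 9900, by = 100), kind = "IC",
                       side = rep(c("L", "R"), 50), source = "truth")
  det <- truth[1:99, ]; det$source <- "x"
  m <- match_events(truth, det)
  expect_equal(sensitivity(m, "IC"), 99)
  expect_equal(laterality_accuracy(m), 100)
  # all missed
  none <- gait_events(source = "x")
  expect_equal(sensitivity(match_events(truth, none), "IC"), 0)
  expect_true(is.na(sensitivity(match_events(none, det), "IC")))
  # 9 of 10 sides agree
  det2 <- truth[1:10, ]; det2$source <- "x"
  det2$side[4] <- ifelse(det2$side[4] == "L", "R", "L")
  expect_equal(laterality_accuracy(match_events(truth[1:10, ], det2)), 90)
  expect_true(sensitivity(m) >= 0 && sensitivity(m) <= 100)
})

test_that("random sides give chance-level laterality accuracy", {
  set.seed(17)
  n <- 1000
  truth <- gait_events(sample = seq_len(n) * 100,
                       kind = "IC", side = sample(c("L", "R"), n, TRUE),
                       source = "truth")
  det <- truth; det$source <- "x"
  det$side <- sample(c("L", "R"), n, TRUE)
  acc <- laterality_accuracy(match_events(truth, det))
  expect_gt(acc, 45); expect_lt(acc, 55)
})

test_that("self-evaluation gives exactly zero temporal errors", {
  sim <- simulate_trial(gait_sim_config(n_cycles = 8, seed = 5))
  ev <- sim$truth$events
  cy <- build_cycles(ev, 100)
  st <- temporal_error_stats(cy, cy, match_events(ev, ev))
  expect_equal(st$mae_ms, rep(0, 3))
  expect_equal(st$mse_ms, rep(0, 3))
  expect_gte(min(st$n), 1)
})

test_that("a uniform 20 ms IC delay shifts stance and swing but not stride", {
  sim <- simulate_trial(gait_sim_config(n_cycles = 10, seed = 6))
  truth <- sim$truth$events
  late <- truth
  late$sample[late$kind == "IC"] <- late$sample[late$kind == "IC"] + 2L
  late$source <- "x"
  m <- match_events(truth, late)
  st <- temporal_error_stats(build_cycles(truth, 100), build_cycles(late, 100), m)
  expect_equal(st$mse_ms[st$param == "stride"], 0)
  expect_equal(st$mse_ms[st$param == "stance"], -20)
  expect_equal(st$mse_ms[st$param == "swing"], 20)
  expect_gte(st$mae_ms[1], abs(st$mse_ms[1]))
})

test_that("uniform detector jitter reproduces the analytic error variance", {
  # ICs jittered by U(-30, 30) ms; stride error is a difference of two
  # independent uniforms: mean 0, sd sqrt(2) * 60/sqrt(12) ms
  set.seed(23)
  n_ev <- 600
  ic_s <- seq_len(n_ev) * 110
  truth <- gait_events(sample = c(ic_s, ic_s + 30),
                       kind = rep(c("IC", "TC"), each = n_ev),
                       side = c(rep(c("L", "R"), n_ev / 2), rep("U", n_ev)),
                       source = "truth")
  jit <- truth
  is_ic <- jit$kind == "IC"
  jit$sample[is_ic] <- jit$sample[is_ic] + sample(-3:3, n_ev, TRUE)
  jit <- gait_events(jit$sample, jit$kind, jit$side, source = "x")
  m <- match_events(truth, jit)
  st <- temporal_error_stats(build_cycles(truth, 100), build_cycles(jit, 100), m)
  stride <- st[st$param == "stride", ]
  expect_gte(stride$n, 500)
  expect_lte(abs(stride$mse_ms), 3)
  # discrete uniform on a +/- 3-sample grid: sd = 20 ms per IC, sqrt(2) x
  # that for the difference of the two bounding ICs
  sd_theory <- sqrt(2) * 20
  expect_lt(abs(stride$sd_se_ms - sd_theory) / sd_theory, 0.15)
})
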