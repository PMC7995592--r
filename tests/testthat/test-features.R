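rate <- 45

test_that("amplitude statistics match definitions", {
  s <- amplitude_stats(rep(0.5, 10))
  expect_equal(unlist(s), c(max = 0.5, min = 0.5, range = 0, rms = 0.5))

  # zero-mean sinusoid over integer periods: rms 1/sqrt(2), range 2
  x <- sin(2 * pi * (0:899) / 45)  # 20 integer periods
  s2 <- amplitude_stats(x)
  expect_equal(s2$rms, 1 / sqrt(2), tolerance = 1e-3)
  expect_equal(s2$range, 2, tolerance = 1e-3)

  set.seed(1)
  y <- rnorm(200)
  s3 <- amplitude_stats(y)
  expect_equal(s3$max, max(y))
  expect_equal(s3$range, max(y) - min(y))
  expect_equal(s3$rms, sqrt(sum(y^2) / 200), tolerance = 1e-12)
  # rms >= |mean| always
  expect_gte(s3$rms, abs(mean(y)))
  expect_error(amplitude_stats(numeric()), class = "tug_argument_error")
})

test_that("transition split finds the opposite-sign valley or falls back", {
  # piecewise-linear SiSt-like segment: valley (negative) at 40%, apex at end
  n <- 100
  valley_at <- 40
  seg <- c(seq(0, -0.1, length.out = valley_at),
           seq(-0.1, 0.4, length.out = n - valley_at + 1)[-1])
  sp <- split_transition(seg, "sist", rate)
  expect_lte(abs(sp - valley_at), 1)

  # monotone segment: midpoint fallback
  mono <- seq(0, 0.4, length.out = n)
  expect_equal(split_transition(mono, "sist", rate), 50)

  # mirrored StSi: apex at start, valley at 60%
  seg2 <- rev(seg)
  sp2 <- split_transition(seg2, "stsi", rate)
  expect_lte(abs(sp2 - (n - valley_at + 1)), 1)

  # splits always strictly interior over random fixtures
  set.seed(2)
  for (i in 1:20) {
    z <- cumsum(rnorm(60, 0, 0.05))
    s <- split_transition(z, sample(c("sist", "stsi"), 1), rate)
    expect_gt(s, 1); expect_lt(s, 60)
  }
  expect_error(split_transition(rnorm(10), "sist", rate),
               class = "tug_argument_error")
})

test_that("jerk features are least-squares slopes of the two parts", {
  # part 1 an exact ramp of 2 g/s, part 2 of 5 g/s
  t1 <- (0:44) / rate; t2 <- (0:59) / rate
  seg <- c(2 * t1, 5 * t2)
  jf <- jerk_features(seg, split = 46, rate = rate)
  expect_equal(jf$max_jerk, 5, tolerance = 1e-9)
  expect_equal(jf$mean_jerk, 3.5, tolerance = 1e-9)
  expect_equal(jf$delta_jerk, 3, tolerance = 1e-9)

  # equal slopes: delta 0
  seg2 <- c(1.5 * t1, 1.5 * t2)
  jf2 <- jerk_features(seg2, 46, rate)
  expect_equal(jf2$delta_jerk, 0, tolerance = 1e-9)
  expect_equal(jf2$max_jerk, 1.5, tolerance = 1e-9)

  # noisy ramps vs closed-form normal-equation oracle
  set.seed(3)
  noisy <- seg + rnorm(length(seg), 0, 0.01)
  jf3 <- jerk_features(noisy, 46, rate)
  ls_slope <- function(y) {
    t <- (seq_along(y) - 1) / rate
    sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
  }
  o1 <- ls_slope(noisy[1:45]); o2 <- ls_slope(noisy[46:105])
  expect_equal(jf3$max_jerk, max(o1, o2), tolerance = 1e-9)
  expect_equal(jf3$delta_jerk, o2 - o1, tolerance = 1e-9)

  expect_error(jerk_features(seg, 2, rate), class = "tug_argument_error")
})

test_that("step detection finds vertical-axis peaks at the step rate", {
  # 2 Hz sinusoid, 5 s: 10 +/- 1 events, step times ~0.5 s
  tt <- (0:(5 * rate - 1)) / rate
  v <- sin(2 * pi * 2 * tt)
  st <- detect_steps(v, rate)
  expect_lte(abs(length(st$events) - 10), 1)
  expect_equal(median(st$step_times), 0.5, tolerance = 0.03)

  expect_error(detect_steps(rep(1, 5 * rate), rate), class = "tug_step_error")

  # definitional step/stride times from known events
  ss <- step_series(c(0.5, 1.0, 1.6))
  expect_equal(ss$step_times, c(0.5, 0.6))
  expect_equal(ss$stride_times, 1.1)
})

test_that("spatiotemporal gait features follow their defining formulas", {
  ss <- step_series(seq(0.25, by = 0.5, length.out = 10))
  g <- gait_spatiotemporal(ss, walk_duration = 5, path_length = 6)
  expect_equal(g$step_length, 0.6)
  expect_equal(g$cadence, 120)
  expect_equal(g$gait_speed, 1.2)
  expect_equal(g$cv_step, 0)  # identical step times

  # alternating 0.5/0.6 step times vs direct sd/mean oracle
  ev <- cumsum(c(0, rep(c(0.5, 0.6), 4)))
  g2 <- gait_spatiotemporal(step_series(ev), 5, 6)
  steps <- diff(ev)
  expect_equal(g2$cv_step, sd(steps) / mean(steps), tolerance = 1e-12)
  strides <- diff(ev, lag = 2)
  expect_equal(g2$cv_stride, sd(strides) / mean(strides), tolerance = 1e-12)

  # too few events for CVs: flagged missing, not zero
  g3 <- gait_spatiotemporal(step_series(c(0.3, 0.9, 1.4)), 5, 6)
  expect_true(is.na(g3$cv_step))
  expect_true(is.na(g3$cv_stride))
})

test_that("FFT features match single-tone closed forms and a spectrum oracle", {
  tt <- (0:(10 * rate - 1)) / rate
  # pure 2 Hz tone: dominant 2.0 Hz within one bin (0.1 Hz)
  expect_equal(fft_dominant(sin(2 * pi * 2 * tt), rate), 2, tolerance = 0.1)
  # 1 Hz (amp 1) + 3 Hz (amp 2): dominant 3 Hz
  two <- sin(2 * pi * tt) + 2 * sin(2 * pi * 3 * tt)
  expect_equal(fft_dominant(two, rate), 3, tolerance = 0.1)
  expect_error(fft_dominant(rep(1, 450), rate), class = "tug_numeric_error")

  # first-quartile percentage: quartile bound is Nyquist/4 = 5.625 Hz
  expect_gt(fft_first_quartile(sin(2 * pi * 1 * tt), rate), 95)
  expect_lt(fft_first_quartile(sin(2 * pi * 10 * tt), rate), 5)

  # broadband fixture vs cumulative-magnitude brute force
  set.seed(5)
  x <- rnorm(450)
  n <- length(x)
  mag <- Mod(fft(x - mean(x)))
  k <- 2:(floor(n / 2) + 1)
  freqs <- (k - 1) * rate / n
  oracle <- 100 * sum(mag[k][freqs <= rate / 8]) / sum(mag[k])
  expect_equal(fft_first_quartile(x, rate), oracle, tolerance = 1e-9)
  expect_gte(oracle, 0); expect_lte(oracle, 100)
})

test_that("REOH reflects the even/odd harmonic balance", {
  tt <- (0:(10 * rate - 1)) / rate
  f0 <- 1  # stride frequency
  # equal power at f0 (odd) and 2 f0 (even): ratio ~ 1
  x <- sin(2 * pi * f0 * tt) + sin(2 * pi * 2 * f0 * tt)
  expect_equal(reoh(x, rate, f0), 1, tolerance = 0.15)
  # pure fundamental: numerator empty
  expect_lt(reoh(sin(2 * pi * f0 * tt), rate, f0), 0.05)

  # random signal vs brute-force harmonic-bin summation
  set.seed(6)
  y <- rnorm(450)
  n <- length(y)
  mag <- Mod(fft(y - mean(y)))
  harm <- 1:20
  harm <- harm[harm * f0 < rate / 2]
  bins <- pmax(2, pmin(round(harm * f0 * n / rate) + 1, floor(n / 2) + 1))
  oracle <- sum(mag[bins][harm %% 2 == 0]) / sum(mag[bins][harm %% 2 == 1])
  expect_equal(reoh(y, rate, f0), oracle, tolerance = 1e-9)

  expect_error(reoh(y, rate, 0), class = "tug_argument_error")
  expect_error(reoh(y[1:45], rate, 0.05), class = "tug_argument_error")
})

test_that("extraction fills the complete 67-feature registry deterministically", {
  sc <- sim_calibrated(seed = 8)
  seg <- segment_tug(sc$rec)
  part <- participant_record("p1", 74, 1, sc$rec,
                             sfbbs_record(c(4, 4, 2, 4, 2, 2, 0)))
  fv <- extract_features(part, seg)

  reg <- feature_registry()
  expect_length(fv, 67)
  expect_identical(names(fv), reg$name)
  expect_equal(nrow(reg), 67)
  expect_false(any(duplicated(reg$name)))  # registry is a bijection
  expect_identical(reg$index, 1:67)

  # composition: features 27-29 equal the gait_spatiotemporal outputs
  wv <- sc$rec$samples[seg$p2:(seg$p3 - 1), "v"]
  st <- detect_steps(wv - mean(wv), 45)
  g <- gait_spatiotemporal(st, seg$durations$walk, 6)
  expect_equal(unname(fv["walk_step_length_m"]), g$step_length)
  expect_equal(unname(fv["walk_cadence"]), g$cadence)
  expect_equal(unname(fv["walk_gait_speed"]), g$gait_speed)

  # feature 65 is the population SD of the two transition durations
  expect_equal(unname(fv["transition_duration_sd"]),
               abs(seg$durations$sist - seg$durations$stsi) / 2)
  # demographics pass through
  expect_equal(unname(fv["age"]), 74)
  expect_equal(unname(fv["gender"]), 1)
  # durations positive; range identity per axis and segment
  expect_gt(fv["tug_duration"], 0)
  for (p in c("sist", "stsi")) for (a in c("v", "ml", "ap"))
    expect_equal(unname(fv[paste0(p, "_range_", a)]),
                 unname(fv[paste0(p, "_max_", a)] -
                          fv[paste0(p, "_min_", a)]))

  # determinism: identical input, identical vector
  expect_identical(fv, extract_features(part, seg))
})

test_that("extraction recovers the simulator's gait parameters within 5%", {
  for (s in c(12, 31)) {
    cfg <- sim_config(seed = s, gait_speed = 1.1, cadence = 110,
                      noise_sd = 0.02)
    sim <- simulate_recording(cfg)
    rec <- calibrate(sim$recording, c(0, 1.8))
    seg <- segment_tug(rec)
    part <- participant_record("x", 70, 0, rec)
    fv <- extract_features(part, seg)
    # ground truth realized by the generator (step jitter can drop a step)
    true_cadence <- 60 * sim$truth$n_steps / sim$truth$durations$walk
    expect_lt(abs(fv["walk_gait_speed"] - 1.1) / 1.1, 0.05)
    expect_lt(abs(fv["walk_cadence"] - true_cadence) / true_cadence, 0.05)
  }
})
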