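# Synchronization, swing cleaning, event detection, trimming, splitting.

test_that("swing-noise cleaning applies the threshold rule exactly", {
  pl <- plantar_stream(148, c(0, 4, 12, 30, 8, 0),
                       c(NA, NA, 1, 2, NA, NA), c(NA, NA, 0.1, 0.2, NA, NA))
  out <- clean_swing_noise(pl, 10)
  expect_equal(out$grf_n, c(0, 0, 12, 30, 0, 0))
  expect_identical(is.na(out$cop_ap_cm), c(T, T, F, F, T, T))

  zero <- plantar_stream(148, numeric(6), rep(NA_real_, 6), rep(NA_real_, 6))
  expect_identical(clean_swing_noise(zero, 10), zero)
  expect_error(clean_swing_noise(pl, 0), "positive")
})

test_that("event thresholds match a brute-force scan of a triangular pulse", {
  # GRF rises 0 -> 600 N over frames 100-160 and falls 600 -> 0 over 160-220.
  n <- 320
  grf <- numeric(n)
  grf[100:160] <- seq(0, 600, length.out = 61)
  grf[160:220] <- seq(600, 0, length.out = 61)
  pl <- plantar_stream(148, grf, rep(NA_real_, n), rep(NA_real_, n))
  ev <- detect_gait_events(pl, 10, 25)

  # independent oracle: scan the constructed ramp directly
  sup <- which(grf > 0)
  hs_oracle <- sup[which(grf[sup] >= 10)[1]]
  pk <- sup[which.max(grf[sup])]
  to_oracle <- (pk:n)[which(grf[pk:n] < 25)[1]]
  expect_equal(nrow(ev), 1)
  expect_equal(ev$hs_frame, hs_oracle)
  expect_equal(ev$to_frame, to_oracle)
})

test_that("no contact means no events", {
  pl <- plantar_stream(148, numeric(500), rep(NA_real_, 500),
                       rep(NA_real_, 500))
  expect_equal(nrow(detect_gait_events(pl)), 0)
})

test_that("detection recovers the generator's truth annotations", {
  s <- generate_session(gait_params(n_steps = 20, seed = 8,
                                    lag_frames = 0))
  ev <- detect_gait_events(clean_swing_noise(s$plantar, 10))
  expect_equal(ev$hs_frame, s$truth_steps$hs_frame)
  expect_equal(ev$to_frame, s$truth_steps$to_frame)
  expect_equal(ev$next_hs_frame, s$truth_steps$next_hs_frame)

  # idempotence: cleaning an already clean stream changes nothing
  cl <- clean_swing_noise(s$plantar, 10)
  expect_identical(clean_swing_noise(cl, 10), cl)
  # rule compliance on every detected stance
  expect_true(all(s$plantar$grf_n[ev$hs_frame] >= 10))
  expect_true(all(s$plantar$grf_n[ev$to_frame] < 25))
})

test_that("synchronization recovers constructed lags exactly", {
  for (lag in c(0L, 17L, -23L)) {
    s <- generate_session(tiny_params(seed = 40 + lag, lag_frames = lag))
    sync <- synchronize(s$sensors, s$plantar)
    expect_equal(sync$lag_frames, lag)
  }
  # after alignment the heel stomp peak coincides with the GRF peak
  s <- generate_session(tiny_params(seed = 77, lag_frames = 17))
  sync <- synchronize(s$sensors, s$plantar)
  pre <- seq_len(round(1.5 * 50))
  accmag <- sqrt(rowSums(sync$sensors$H$channels[pre, 1:3]^2))
  expect_equal(which.max(accmag), which.max(s$plantar$grf_n[pre]))
})

test_that("random lags are recovered exactly across 100 seeded sessions", {
  lags <- integer(100)
  truth <- integer(100)
  for (i in 1:100) {
    s <- generate_session(tiny_params(n_steps = 2, seed = 1000 + i))
    truth[i] <- s$lag_frames
    lags[i] <- synchronize(s$sensors, s$plantar)$lag_frames
  }
  expect_identical(lags, truth)
  # the generator really does exercise both signs of lag
  expect_true(any(truth > 0) && any(truth < 0))
})

test_that("synchronization fails without a stomp", {
  n <- 600
  flat <- plantar_stream(148, numeric(n), rep(NA_real_, n), rep(NA_real_, n))
  sens <- constant_sensors(n)
  expect_error(synchronize(sens, flat), "prominence")
  expect_error(synchronize(sens["T"], flat), "heel sensor")
})

test_that("edge-step trimming removes n_edge steps per trip end", {
  mk <- function(n, offset = 0) data.frame(
    step_idx = seq_len(n) + offset,
    hs_frame = offset * 1000 + seq_len(n) * 100,
    to_frame = offset * 1000 + seq_len(n) * 100 + 60,
    next_hs_frame = NA)
  expect_equal(nrow(trim_steps(mk(40))), 34)
  expect_warning(out <- trim_steps(mk(6)), "dropped")
  expect_equal(nrow(out), 0)

  two <- rbind(mk(40), mk(40, offset = 40))
  expect_equal(nrow(trim_steps(two, trip_boundaries = 40 * 1000)), 68)
})

test_that("step splitting is a reproducible 70/30 partition", {
  steps <- data.frame(step_idx = 1:74, hs_frame = 1:74 * 100,
                      to_frame = 1:74 * 100 + 60, next_hs_frame = NA)
  sp <- split_steps(steps, 0.7, seed = 5)
  expect_equal(length(sp$train_steps), 52)
  expect_equal(length(sp$test_steps), 22)
  expect_identical(sp, split_steps(steps, 0.7, seed = 5))
  for (seed in 1:5) {
    sp <- split_steps(steps, 0.7, seed = seed)
    expect_length(intersect(sp$train_steps, sp$test_steps), 0)
    expect_setequal(c(sp$train_steps, sp$test_steps), steps$step_idx)
  }
  expect_error(split_steps(steps, 1.2), "fraction")
  expect_error(split_steps(steps[1, ], 0.7), "at least 2")
})

test_that("the COP centroid is the pressure-weighted mean", {
  expect_equal(compute_cop_centroid(5, 3.0, 1.0),
               c(cop_ap_cm = 3.0, cop_ml_cm = 1.0))
  expect_equal(compute_cop_centroid(c(2, 2), c(0, 10), c(0, 0))[["cop_ap_cm"]],
               5.0)
  expect_equal(compute_cop_centroid(c(1, 2, 3), c(0, 1, 2),
                                    c(0, 0, 0))[["cop_ap_cm"]],
               (0 + 2 + 6) / 6)
  expect_error(compute_cop_centroid(c(0, 0), c(0, 1), c(0, 1)), "undefined")
})
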