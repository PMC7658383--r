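# Synthetic gait generator: calibration, determinism, session structure.

test_that("noise-free step templates are deterministic and phase-coupled", {
  p <- gait_params(imu_noise_sd = 0, step_scale_sd = 0)
  set.seed(5)
  a <- generate_step(p)
  set.seed(5)
  b <- generate_step(p)
  expect_identical(a, b)

  # With zero jitter the stance COP is an exact function of latent phase:
  # two steps with the same stance length have identical COP curves.
  set.seed(5)
  c <- generate_step(p)
  expect_identical(a$cop_ap, c$cop_ap)
  expect_identical(a$cop_ml, c$cop_ml)

  # GRF support is exactly the stance; swing COP is the NA sentinel.
  ns <- a$stance_frames
  expect_true(all(a$grf[seq_len(ns)] > 0))
  expect_true(all(a$grf[-seq_len(ns)] == 0))
  expect_true(all(is.na(a$cop_ap[-seq_len(ns)])))
  expect_true(all(diff(a$cop_ap[seq_len(ns)]) >= 0))
})

test_that("step templates reproduce the calibrated COP geometry", {
  set.seed(7)
  p <- gait_params()
  steps <- replicate(300, generate_step(p), simplify = FALSE)
  ap <- vapply(steps, function(s) {
    v <- s$cop_ap[seq_len(s$stance_frames)]
    v[length(v)] - v[1]
  }, numeric(1))
  ml <- vapply(steps, function(s) {
    v <- s$cop_ml[seq_len(s$stance_frames)]
    max(v) - min(v)
  }, numeric(1))
  expect_lt(abs(mean(ap) - 17.48), 3 * sd(ap) / sqrt(length(ap)) + 0.05)
  expect_lt(abs(mean(ml) - 1.48), 3 * sd(ml) / sqrt(length(ml)) + 0.01)
})

test_that("stance lengths follow the stated normal law", {
  p <- gait_params()
  set.seed(11)
  ns <- replicate(500, generate_step(p)$stance_frames)
  # Monte-Carlo check against the sampling law (2 SE band, plus rounding).
  expect_lt(abs(mean(ns) - p$stance_frames_mean),
            2 * p$stance_frames_sd / sqrt(500) + 0.5)
})

test_that("sessions carry the requested number of ordered, disjoint steps", {
  s <- generate_session(gait_params(n_steps = 74, seed = 3))
  expect_equal(nrow(s$truth_steps), 74)
  expect_true(all(diff(s$truth_steps$hs_frame) > 0))
  expect_true(all(s$truth_steps$hs_frame < s$truth_steps$to_frame))
  # stance slices disjoint: each step ends before the next begins
  expect_true(all(s$truth_steps$to_frame[-74] <=
                    s$truth_steps$hs_frame[-1]))
  # next_hs recorded for all but the last step
  expect_true(all(!is.na(s$truth_steps$next_hs_frame[-74])))
  expect_true(is.na(s$truth_steps$next_hs_frame[74]))
})

test_that("same seed gives a bitwise-identical session", {
  p <- tiny_params(seed = 99)
  expect_identical(generate_session(p), generate_session(p))
})

test_that("stance GRF peaks stay near body weight", {
  s <- generate_session(gait_params(seed = 13))
  peaks <- vapply(seq_len(nrow(s$truth_steps)), function(k) {
    f <- s$truth_steps$hs_frame[k]:(s$truth_steps$to_frame[k] - 1)
    max(s$plantar$grf_n[f])
  }, numeric(1))
  expect_true(all(peaks >= 0.9 * 541 & peaks <= 1.3 * 541))
})

test_that("the stomp aligns heel IMU and GRF argmax per the chosen lag", {
  p0 <- tiny_params(seed = 21, lag_frames = 0)
  s0 <- generate_session(p0)
  pre <- seq_len(round(1.5 * p0$sample_rate_hz))
  accmag <- sqrt(rowSums(s0$sensors$H$channels[pre, 1:3]^2))
  expect_equal(which.max(accmag), which.max(s0$plantar$grf_n[pre]))

  s17 <- generate_session(tiny_params(seed = 21, lag_frames = 17))
  accmag <- sqrt(rowSums(s17$sensors$H$channels[pre, 1:3]^2))
  expect_equal(which.max(accmag) - which.max(s17$plantar$grf_n[pre]), 17)
})

test_that("corrupt_swing only touches swing frames and zero noise is identity", {
  s <- generate_session(tiny_params(seed = 31))
  expect_identical(corrupt_swing(s$plantar, 0), s$plantar)

  set.seed(1)
  cor <- corrupt_swing(s$plantar, noise_sd = 2, prob = 0.5)
  stance <- which(s$plantar$grf_n > 0)
  expect_identical(cor$grf_n[stance], s$plantar$grf_n[stance])
  swing <- which(s$plantar$grf_n == 0)
  expect_gt(sum(cor$grf_n[swing] > 0), 0)

  # Round-trip through the cleaning rule: corrupted frames below 10 N
  # return to zero, stance frames bitwise unchanged.
  cleaned <- clean_swing_noise(cor, threshold_n = 10)
  low <- swing[cor$grf_n[swing] < 10]
  expect_true(all(cleaned$grf_n[low] == 0))
  expect_identical(cleaned$grf_n[stance], s$plantar$grf_n[stance])
})

test_that("invalid generator parameters are rejected", {
  expect_error(gait_params(sample_rate_hz = 0), "positive")
  expect_error(gait_params(stance_frames_mean = 170), "cycle_frames_mean")
  expect_error(gait_params(imu_noise_sd = -1), "non-negative")
})
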