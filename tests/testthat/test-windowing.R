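# Window construction, lookback period, standardization, sizing.

test_that("the lookback period is the mean cycle length", {
  steps <- data.frame(step_idx = 1:2, hs_frame = c(1, 161),
                      to_frame = c(120, 280),
                      next_hs_frame = c(161, 327))
  expect_equal(mean_step_period(steps), 163)  # mean of 160, 166

  single <- data.frame(step_idx = 1, hs_frame = 10, to_frame = 100,
                       next_hs_frame = 158)
  expect_equal(mean_step_period(single), 148)
  none <- data.frame(step_idx = 1, hs_frame = 10, to_frame = 100,
                     next_hs_frame = NA)
  expect_error(mean_step_period(none), "successor")
})

test_that("zero-jitter sessions give exactly the nominal cycle length", {
  s <- generate_session(gait_params(n_steps = 50, stance_frames_sd = 0,
                                    step_scale_sd = 0, seed = 9))
  ev <- detect_gait_events(clean_swing_noise(s$plantar, 10))
  expect_equal(mean_step_period(ev), 163)
})

test_that("one full-history step of 120 stance frames gives 120 samples", {
  n <- 400
  sens <- constant_sensors(n, value = 0.5)
  hs <- 250
  pl <- pulse_plantar(n, hs, hs + 120)
  steps <- data.frame(step_idx = 1, hs_frame = hs, to_frame = hs + 120,
                      next_hs_frame = NA)
  spec <- window_spec("T", "AP", lookback_frames = 163)
  smp <- build_samples(sens, pl, steps, spec)
  expect_equal(length(smp$y), 120)
  expect_equal(dim(smp$x), c(120, 6, 163))
  # constant channels produce constant window content
  expect_true(all(smp$x == 0.5))
  expect_equal(sample_matrix(smp, 3), matrix(0.5, 163, 6))
  # targets are the stance COP at the predicted frame
  expect_equal(smp$y, pl$cop_ap_cm[smp$frame_idx])
})

test_that("the full four-site stack has 24 feature columns in H,L,T,W order", {
  n <- 300
  sens <- constant_sensors(n)
  for (i in seq_along(sens)) sens[[i]]$channels[] <- i  # H=1 L=2 T=3 W=4
  pl <- pulse_plantar(n, 200, 260)
  steps <- data.frame(step_idx = 1, hs_frame = 200, to_frame = 260,
                      next_hs_frame = NA)
  spec <- window_spec(c("W", "T", "H", "L"), "AP", 150)  # order-insensitive
  smp <- build_samples(sens, pl, steps, spec)
  expect_equal(smp$spec$feature_dim, 24)
  expect_equal(unname(smp$x[1, , 1]), rep(1:4, each = 6))
})

test_that("sample counts match a brute-force enumerator and skip short history", {
  s <- generate_session(tiny_params(n_steps = 5, seed = 14))
  ev <- detect_gait_events(clean_swing_noise(s$plantar, 10))
  for (P in c(10, 30, 200)) {
    spec <- window_spec("H", "AP", P)
    expected <- count_windows_bruteforce(ev, P, length(s$plantar$grf_n))
    if (expected == 0) {
      expect_error(build_samples(s$sensors, s$plantar, ev, spec), "empty")
    } else {
      smp <- build_samples(s$sensors, clean_swing_noise(s$plantar, 10),
                           ev, spec)
      expect_equal(length(smp$y), expected)
      # prediction frames all lie inside their step's stance
      for (i in seq_along(smp$y)) {
        st <- ev[ev$step_idx == smp$step_idx[i], ]
        expect_true(smp$frame_idx[i] >= st$hs_frame &&
                      smp$frame_idx[i] < st$to_frame)
      }
    }
  }
})

test_that("standardization uses training statistics and is leakage-free", {
  s <- generate_session(tiny_params(n_steps = 8, seed = 15))
  ev <- detect_gait_events(clean_swing_noise(s$plantar, 10))
  spec <- window_spec(c("H", "T"), "AP", 30)
  smp <- build_samples(s$sensors, clean_swing_noise(s$plantar, 10), ev, spec)
  sp <- split_steps(ev, 0.7, seed = 2)

  train <- standardize_samples(subset_samples(smp, step_ids = sp$train_steps))
  stats <- attr(train, "stats")
  # training moments ~ N(0, 1) per channel
  for (j in seq_len(dim(train$x)[2])) {
    expect_lt(abs(mean(train$x[, j, ])), 1e-6)
    expect_lt(abs(sd(train$x[, j, ]) - 1), 1e-6)
  }
  # direct formula: value 6 under mean 2 / sd 4 maps to 1.0
  fake <- subset_samples(smp, step_ids = sp$test_steps)
  fake$x[] <- 6
  out <- standardize_samples(fake, list(mean = rep(2, 12), sd = rep(4, 12)))
  expect_true(all(out$x == 1.0))
  # no test step contributes to the training stats (provenance disjoint)
  expect_length(intersect(unique(train$step_idx), sp$test_steps), 0)
  # re-applying the same stats is a different contract than re-deriving
  twice <- standardize_samples(train, stats)
  expect_false(isTRUE(all.equal(twice$x, train$x)))
})

test_that("zero-variance channels are centered with a warning", {
  s <- generate_session(tiny_params(n_steps = 4, seed = 16, imu_noise_sd = 0))
  ev <- detect_gait_events(clean_swing_noise(s$plantar, 10))
  smp <- build_samples(s$sensors, clean_swing_noise(s$plantar, 10), ev,
                       window_spec("W", "AP", 20))
  smp$x[, 2, ] <- 7  # constant channel
  expect_warning(out <- standardize_samples(smp), "zero-SD")
  expect_true(all(out$x[, 2, ] == 0))
})

test_that("the study sizing arithmetic reproduces the training matrix rows", {
  expect_equal(training_matrix_rows(5, 74, 148, 0.7), 38332)
})
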