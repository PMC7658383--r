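# LSTM regressor: learnability, determinism, causality, rollout.

# Noise-free linear functional of the window, as a learnability target.
linear_samples <- function(n = 500, d = 6, P = 10, seed = 3) {
  set.seed(seed)
  x <- array(rnorm(n * d * P), dim = c(n, d, P))
  y <- 0.8 * x[, 1, P] - 0.5 * x[, 3, P - 1] + 0.3 * x[, 2, P]
  structure(list(x = x, y = y, step_idx = rep(1L, n),
                 frame_idx = seq_len(n),
                 spec = window_spec("T", "AP", P)),
            class = "windowed_samples")
}

test_that("the network learns a noise-free linear functional", {
  smp <- linear_samples()
  cfg <- model_config(epochs = 20, batch_size = 32, dropout_rate = 0,
                      seed = 7)
  fit <- train_copnet(smp, cfg)
  expect_length(fit$training_history, 20)
  final_rmse <- fit$training_history[20] * fit$y_scale
  expect_lt(final_rmse, 0.05 * diff(range(smp$y)))
  # the recorded history is the per-epoch loss and broadly decreases
  expect_lt(fit$training_history[20], fit$training_history[1])
})

test_that("capacity sanity: 200 samples are overfit within 20 epochs", {
  smp <- linear_samples(n = 200, seed = 8)
  fit <- train_copnet(smp, model_config(epochs = 20, batch_size = 32,
                                        dropout_rate = 0, seed = 9))
  final_rmse <- fit$training_history[20] * fit$y_scale
  expect_lt(final_rmse, 0.10 * diff(range(smp$y)))
})

test_that("training is reproducible under a fixed seed", {
  smp <- linear_samples(n = 120, P = 8)
  cfg <- model_config(epochs = 3, batch_size = 32, seed = 11)
  a <- train_copnet(smp, cfg)
  b <- train_copnet(smp, cfg)
  expect_identical(a$training_history, b$training_history)
  expect_identical(predict(a, smp), predict(b, smp))
})

test_that("a zero-target model predicts approximately zero", {
  smp <- linear_samples(n = 200, P = 8)
  smp$y <- rep(0, 200)
  fit <- train_copnet(smp, model_config(epochs = 5, batch_size = 32,
                                        seed = 12))
  expect_lt(max(abs(predict(fit, smp))), 0.15)
})

test_that("invalid configurations and shapes are rejected", {
  expect_error(model_config(epochs = 0), "epochs")
  expect_error(model_config(dropout_rate = 1), "dropout")
  expect_error(model_config(hidden_sizes = integer(0)), "hidden")
  smp <- linear_samples(n = 20, P = 5)
  smp$spec$feature_dim <- 12L
  expect_error(train_copnet(smp, tiny_config()), "shape")
})

test_that("trajectory rollout is causal and one value per stance frame", {
  s <- generate_session(tiny_params(n_steps = 6, seed = 18, lag_frames = 0))
  pl <- clean_swing_noise(s$plantar, 10)
  ev <- detect_gait_events(pl)
  spec <- window_spec("T", "AP", 30)
  smp <- standardize_samples(build_samples(s$sensors, pl, ev, spec))
  fit <- train_copnet(smp, tiny_config(epochs = 2))

  st <- ev[3, ]
  traj <- predict_trajectory(fit, s$sensors, st)
  expect_length(traj, st$to_frame - st$hs_frame)

  # Perturbing IMU frames at or after t leaves predictions before and at t
  # unchanged (many-to-one windows end strictly before the target frame).
  t_mid <- st$hs_frame + 10L
  pert <- s$sensors
  for (site in names(pert))
    pert[[site]]$channels[t_mid:nrow(pert[[site]]$channels), ] <- 99
  traj_pert <- predict_trajectory(fit, pert, st)
  n_before <- t_mid - st$hs_frame + 1L   # frames hs .. t_mid
  expect_identical(traj[seq_len(n_before)], traj_pert[seq_len(n_before)])
  expect_false(identical(traj, traj_pert))
})

test_that("rollout covers a 120-frame stance when history is complete", {
  n <- 400
  sens <- constant_sensors(n, 0.3)
  st <- data.frame(step_idx = 1, hs_frame = 250, to_frame = 370,
                   next_hs_frame = NA)
  smp <- linear_samples(n = 30, P = 40)
  fit <- train_copnet(smp, tiny_config(epochs = 1))
  traj <- predict_trajectory(fit, sens, st)
  expect_length(traj, 120)
  expect_error(
    predict_trajectory(fit, constant_sensors(30), st), "history")
})
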