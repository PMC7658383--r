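# The recurrent COP regressor: a three-layer LSTM (64/128/64 units) with a
# dropout layer before the linear read-out, trained many-to-one with an
# RMSE loss and RMSprop. The numerical core lives in src/lstm.cpp
# (single-precision, batched BLAS, full backpropagation through time).

#' Model configuration for the LSTM COP regressor
#'
#' @param hidden_sizes Hidden-layer widths, default `c(64, 128, 64)`.
#' @param dropout_rate Dropout probability on the read-out features,
#'   in `[0, 1)`.
#' @param epochs Training epochs (>= 1).
#' @param batch_size Mini-batch size (>= 1); the default 148 covers one
#'   second of frames at the nominal 148 Hz rate.
#' @param learning_rate,rho,epsilon RMSprop hyper-parameters.
#' @param shuffle Reshuffle the sample order every epoch.
#' @param seed Optional integer seed controlling weight initialization,
#'   shuffling and dropout masks; fixed seed gives run-to-run identical
#'   training on one machine.
#' @return A `model_config` object.
#' @export
model_config <- function(hidden_sizes = c(64, 128, 64), dropout_rate = 0.2,
                         epochs = 20, batch_size = 148,
                         learning_rate = 1e-3, rho = 0.9, epsilon = 1e-8,
                         shuffle = TRUE, seed = NULL) {
  if (length(hidden_sizes) < 1 || any(hidden_sizes < 1))
    stop("model_config: hidden sizes must be positive", call. = FALSE)
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("model_config: dropout_rate must be in [0, 1)", call. = FALSE)
  if (epochs < 1) stop("model_config: epochs must be >= 1", call. = FALSE)
  if (batch_size < 1)
    stop("model_config: batch_size must be >= 1", call. = FALSE)
  if (learning_rate <= 0)
    stop("model_config: learning_rate must be positive", call. = FALSE)
  structure(list(hidden_sizes = as.integer(hidden_sizes),
                 dropout_rate = dropout_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, rho = rho,
                 epsilon = epsilon, shuffle = isTRUE(shuffle), seed = seed),
            class = "model_config")
}

#' Train the LSTM COP regressor
#'
#' Fits the three-layer LSTM on windowed samples. Targets are z-scored
#' internally (statistics stored in the model and inverted at prediction
#' time) so that the optimizer works on a unit scale regardless of the COP
#' axis. Per-epoch mean training RMSE (on the standardized scale) is
#' recorded in `training_history`.
#'
#' @param samples A `windowed_samples` object (see [build_samples()];
#'   standardize inputs first with [standardize_samples()]).
#' @param config A [model_config()].
#' @return A `copnet_model`: list with `weights`, `training_history`,
#'   `config`, `direction`, `input_spec`, `y_center`, `y_scale`, `x_stats`.
#' @export
train_copnet <- function(samples, config = model_config()) {
  stopifnot(inherits(samples, "windowed_samples"),
            inherits(config, "model_config"))
  n <- length(samples$y)
  if (n < 1) stop("train_copnet: no samples", call. = FALSE)
  if (dim(samples$x)[1] != n || dim(samples$x)[2] != samples$spec$feature_dim)
    stop("train_copnet: sample array shape does not match its spec",
         call. = FALSE)
  if (any(!is.finite(samples$y)))
    stop("train_copnet: non-finite targets", call. = FALSE)

  y_center <- mean(samples$y)
  y_scale <- sd(samples$y)
  if (!is.finite(y_scale) || y_scale == 0) y_scale <- 1
  yz <- (samples$y - y_center) / y_scale

  fit <- with_seed(config$seed,
    .lstm_train(samples$x, yz, config$hidden_sizes, config$dropout_rate,
                config$epochs, config$batch_size, config$learning_rate,
                config$rho, config$epsilon, config$shuffle))

  structure(list(weights = fit[c("layers", "dense_w", "dense_b")],
                 training_history = as.numeric(fit$history),
                 config = config, direction = samples$spec$direction,
                 input_spec = samples$spec,
                 y_center = y_center, y_scale = y_scale,
                 x_stats = attr(samples, "stats")),
            class = "copnet_model")
}

#' @export
print.copnet_model <- function(x, ...) {
  h <- x$training_history
  cat(sprintf("<copnet_model %s> LSTM %s, %d epochs (final loss %.4f), sites %s, P = %d\n",
              x$direction,
              paste(x$config$hidden_sizes, collapse = "/"), length(h),
              h[length(h)], paste(x$input_spec$sites, collapse = "+"),
              x$input_spec$lookback_frames))
  invisible(x)
}

#' Predict COP values for windowed samples
#'
#' @param object A `copnet_model`.
#' @param samples A `windowed_samples` object with the same feature layout
#'   the model was trained on. If the model carries training-set channel
#'   statistics and the samples are not yet standardized, the training
#'   statistics are applied first.
#' @param ... Unused.
#' @return Numeric vector of COP predictions (cm).
#' @export
predict.copnet_model <- function(object, samples, ...) {
  stopifnot(inherits(samples, "windowed_samples"))
  if (dim(samples$x)[2] != object$input_spec$feature_dim)
    stop("predict.copnet_model: feature dimension mismatch", call. = FALSE)
  if (!is.null(object$x_stats) && !isTRUE(attr(samples, "standardized")))
    samples <- standardize_samples(samples, object$x_stats)
  z <- .lstm_predict(object$weights, samples$x)
  object$y_scale * z + object$y_center
}

#' Predict one step's stance-phase COP trajectory
#'
#' Rolls the many-to-one model frame by frame across a step's stance phase:
#' the prediction at frame `t` uses only IMU frames `[t - P, t)`, so no
#' future information leaks into the trajectory.
#'
#' @param model A `copnet_model`.
#' @param sensors Aligned site-named list of [sensor_stream()].
#' @param step One-row step annotation (or a list with `hs_frame`,
#'   `to_frame`).
#' @return Numeric vector with one predicted COP value (cm) per stance
#'   frame that has full lookback history.
#' @export
predict_trajectory <- function(model, sensors, step) {
  spec <- model$input_spec
  P <- spec$lookback_frames
  ch <- .stack_channels(sensors, spec$sites)
  f <- step$hs_frame[1]:(step$to_frame[1] - 1L)
  f <- f[f - P >= 1 & f <= nrow(ch)]
  if (length(f) == 0)
    stop("predict_trajectory: no stance frame has enough history",
         call. = FALSE)
  x <- array(0, dim = c(length(f), spec$feature_dim, P))
  for (i in seq_along(f))
    x[i, , ] <- t(ch[(f[i] - P):(f[i] - 1L), , drop = FALSE])
  fake <- structure(list(x = x, y = rep(0, length(f)),
                         step_idx = rep(step$step_idx[1] %||% 1L, length(f)),
                         frame_idx = f, spec = spec),
                    class = "windowed_samples")
  predict(model, fake)
}
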