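# Many-to-one window construction: a lookback window of stacked IMU
# channels predicts one stance-phase COP value, advanced frame by frame.

#' Specify the window layout
#'
#' @param sites Subset of `c("H", "L", "T", "W")`; feature columns are
#'   stacked in this canonical order, six channels (`ax, ay, az, gx, gy,
#'   gz`) per site, so the feature dimension is `6 * length(sites)`.
#' @param direction Target COP axis, `"AP"` or `"ML"`.
#' @param lookback_frames Window length P in frames (>= 1); typically the
#'   participant's mean heel-strike-to-heel-strike cycle length, see
#'   [mean_step_period()].
#' @return A `window_spec` object.
#' @export
window_spec <- function(sites, direction = c("AP", "ML"), lookback_frames) {
  direction <- match.arg(direction)
  sites <- SITE_LEVELS[SITE_LEVELS %in% sites]
  if (length(sites) == 0)
    stop("window_spec: 'sites' must contain at least one of H, L, T, W",
         call. = FALSE)
  if (!is.numeric(lookback_frames) || lookback_frames < 1)
    stop("window_spec: lookback_frames must be >= 1", call. = FALSE)
  structure(list(sites = sites, direction = direction,
                 lookback_frames = as.integer(lookback_frames),
                 feature_dim = 6L * length(sites)),
            class = "window_spec")
}

#' Mean heel-strike-to-heel-strike period of the training steps
#'
#' The lookback window length is the participant's mean cycle length,
#' computed on training steps only, rounded to whole frames.
#'
#' @param steps Step annotations with `hs_frame` and `next_hs_frame`.
#' @return Integer number of frames.
#' @export
mean_step_period <- function(steps) {
  ok <- !is.na(steps$next_hs_frame)
  if (!any(ok))
    stop("mean_step_period: no step has a recorded successor", call. = FALSE)
  as.integer(round(mean(steps$next_hs_frame[ok] - steps$hs_frame[ok])))
}

# Stack the selected sites' channel matrices into one n x D matrix.
.stack_channels <- function(sensors, sites) {
  do.call(cbind, lapply(sites, function(s) sensors[[s]]$channels))
}

#' Build many-to-one windowed samples
#'
#' For every step and every stance frame `t` (half-open stance
#' `[hs_frame, to_frame)`) with at least `P = lookback_frames` frames of
#' recorded history, emits one sample: the IMU frames `[t - P, t)` of the
#' selected sites (so the input covers the preceding swing phase and never
#' includes frame `t` itself) paired with the COP value at `t`. Stance
#' frames whose window would start before the recording are skipped rather
#' than padded.
#'
#' @param sensors Site-named list of [sensor_stream()], aligned to the
#'   plantar clock (see [synchronize()]).
#' @param plantar A cleaned [plantar_stream()].
#' @param steps Step annotations to draw target frames from.
#' @param spec A [window_spec()].
#' @return A `windowed_samples` object: list with `x` (array
#'   `N x feature_dim x P`), `y` (COP, cm), `step_idx`, `frame_idx`, `spec`.
#' @export
build_samples <- function(sensors, plantar, steps, spec) {
  stopifnot(inherits(spec, "window_spec"))
  P <- spec$lookback_frames
  ch <- .stack_channels(sensors, spec$sites)
  cop <- if (spec$direction == "AP") plantar$cop_ap_cm else plantar$cop_ml_cm

  frames <- integer(0); sidx <- integer(0)
  for (k in seq_len(nrow(steps))) {
    f <- steps$hs_frame[k]:(steps$to_frame[k] - 1L)
    f <- f[f - P >= 1 & f <= nrow(ch) & f <= length(cop)]
    f <- f[is.finite(cop[f])]
    frames <- c(frames, f)
    sidx <- c(sidx, rep(steps$step_idx[k], length(f)))
  }
  n <- length(frames)
  if (n == 0)
    stop("build_samples: empty dataset, no stance frame has enough history",
         call. = FALSE)

  x <- array(0, dim = c(n, spec$feature_dim, P))
  for (i in seq_len(n))
    x[i, , ] <- t(ch[(frames[i] - P):(frames[i] - 1L), , drop = FALSE])
  structure(list(x = x, y = cop[frames], step_idx = sidx,
                 frame_idx = frames, spec = spec),
            class = "windowed_samples")
}

#' @export
print.windowed_samples <- function(x, ...) {
  cat(sprintf("<windowed_samples> %d samples, %d features x %d frames (%s, sites %s)\n",
              length(x$y), x$spec$feature_dim, x$spec$lookback_frames,
              x$spec$direction, paste(x$spec$sites, collapse = "+")))
  invisible(x)
}

#' Extract one sample as a P x feature_dim matrix
#'
#' @param samples A `windowed_samples` object.
#' @param i Sample index.
#' @return Matrix of `lookback_frames` rows by `feature_dim` columns.
#' @export
sample_matrix <- function(samples, i) t(samples$x[i, , , drop = TRUE])

#' Per-channel z-scoring of windowed samples
#'
#' Standardizes each feature channel to zero mean and unit SD. Statistics
#' are computed over all frames of the given samples unless `stats` is
#' supplied, in which case they are reused — test samples must always be
#' standardized with the training-set statistics.
#'
#' @param samples A `windowed_samples` object.
#' @param stats Optional list `(mean, sd)` of per-channel statistics.
#' @return Standardized samples; the statistics used are attached as
#'   `attr(, "stats")`. Zero-SD channels are centered only, with a warning.
#' @export
standardize_samples <- function(samples, stats = NULL) {
  x <- samples$x
  d <- dim(x)[2]
  if (is.null(stats)) {
    mu <- apply(x, 2, mean)
    sig <- apply(x, 2, sd)
    if (any(sig == 0)) {
      warning("standardize_samples: zero-SD channel(s) centered only",
              call. = FALSE)
      sig[sig == 0] <- 1
    }
    stats <- list(mean = mu, sd = sig)
  }
  for (j in seq_len(d))
    x[, j, ] <- (x[, j, ] - stats$mean[j]) / stats$sd[j]
  samples$x <- x
  attr(samples, "stats") <- stats
  attr(samples, "standardized") <- TRUE
  samples
}

#' Subset samples by step identity or feature columns
#'
#' @param samples A `windowed_samples` object.
#' @param step_ids Keep only samples whose `step_idx` is in this set.
#' @param sites Keep only the feature columns of these sites (must be a
#'   subset of the spec's sites); the spec is updated accordingly.
#' @return The filtered `windowed_samples`.
#' @export
subset_samples <- function(samples, step_ids = NULL, sites = NULL) {
  if (!is.null(step_ids)) {
    keep <- samples$step_idx %in% step_ids
    samples$x <- samples$x[keep, , , drop = FALSE]
    samples$y <- samples$y[keep]
    samples$step_idx <- samples$step_idx[keep]
    samples$frame_idx <- samples$frame_idx[keep]
  }
  if (!is.null(sites)) {
    sites <- SITE_LEVELS[SITE_LEVELS %in% sites]
    if (!all(sites %in% samples$spec$sites))
      stop("subset_samples: 'sites' must be a subset of the spec's sites",
           call. = FALSE)
    cols <- unlist(lapply(sites, function(s) {
      off <- (match(s, samples$spec$sites) - 1L) * 6L
      off + 1:6
    }))
    samples$x <- samples$x[, cols, , drop = FALSE]
    samples$spec <- window_spec(sites, samples$spec$direction,
                                samples$spec$lookback_frames)
  }
  samples
}

#' Training-matrix row count of a study layout
#'
#' Number of training frames implied by a study design: subjects times
#' steps per subject times frames retained per step times the training
#' fraction. For 5 subjects, 74 steps, 148 frames and a 0.7 split this is
#' 38,332 rows.
#'
#' @param n_subjects,steps_per_subject,frames_per_step,train_fraction
#'   Study layout factors.
#' @return The row count (numeric).
#' @export
training_matrix_rows <- function(n_subjects = 5, steps_per_subject = 74,
                                 frames_per_step = 148,
                                 train_fraction = 0.7) {
  n_subjects * steps_per_subject * frames_per_step * train_fraction
}
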