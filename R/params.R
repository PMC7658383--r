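#' Parameters of the synthetic gait generator
#'
#' Bundles every knob of the simulator with defaults calibrated to a typical
#' healthy-adult treadmill-free walking session recorded at 148 Hz: 74
#' analysed left-foot steps, a stance phase of about 120 frames (~0.81 s)
#' within a gait cycle of about 163 frames (~1.1 s), an anterior-posterior
#' COP path of 17.48 cm, a medial-lateral COP excursion of 1.48 cm, and a
#' double-bump vertical ground reaction force scaled to body weight.
#'
#' @param sample_rate_hz Sampling rate shared by all streams (Hz).
#' @param n_steps Number of gait cycles per session.
#' @param stance_frames_mean,stance_frames_sd Normal law (in frames) from
#'   which each step's stance length is drawn.
#' @param cycle_frames_mean Mean heel-strike-to-heel-strike cycle length in
#'   frames. Swing length is held at `cycle_frames_mean - stance_frames_mean`
#'   so per-step length variability enters through the stance draw.
#' @param body_weight_n Body weight in newtons; scales the vertical GRF.
#' @param cop_ap_length_cm Heel-to-toe COP path length per step (cm).
#' @param cop_ml_excursion_cm Medial-lateral COP excursion (max minus min)
#'   per step (cm).
#' @param imu_noise_sd Additive white-noise SD on every IMU channel, as a
#'   fraction of that channel's deterministic amplitude.
#' @param step_scale_sd SD of the per-step amplitude jitter multiplier
#'   (drawn once per step, applied to GRF, COP and IMU alike so that the
#'   IMU-to-COP mapping stays learnable).
#' @param lag_frames Integer offset of the sensor clock relative to the
#'   plantar clock; `NULL` (default) draws it uniformly from -30..30 frames
#'   when a session is generated.
#' @param stomp_amplitude Height of the synchronization stomp spike as a
#'   multiple of the normal gait peak (GRF and heel acceleration alike).
#' @param seed Optional integer seed making session generation reproducible.
#'
#' @return An object of class `gait_params`.
#' @export
#' @examples
#' p <- gait_params(n_steps = 5, seed = 1)
#' s <- generate_session(p)
gait_params <- function(sample_rate_hz = 148,
                        n_steps = 74,
                        stance_frames_mean = 120,
                        stance_frames_sd = 6,
                        cycle_frames_mean = 163,
                        body_weight_n = 541,
                        cop_ap_length_cm = 17.48,
                        cop_ml_excursion_cm = 1.48,
                        imu_noise_sd = 0.05,
                        step_scale_sd = 0.05,
                        lag_frames = NULL,
                        stomp_amplitude = 3,
                        seed = NULL) {
  p <- structure(list(
    sample_rate_hz = sample_rate_hz,
    n_steps = as.integer(n_steps),
    stance_frames_mean = stance_frames_mean,
    stance_frames_sd = stance_frames_sd,
    cycle_frames_mean = cycle_frames_mean,
    body_weight_n = body_weight_n,
    cop_ap_length_cm = cop_ap_length_cm,
    cop_ml_excursion_cm = cop_ml_excursion_cm,
    imu_noise_sd = imu_noise_sd,
    step_scale_sd = step_scale_sd,
    lag_frames = if (is.null(lag_frames)) NULL else as.integer(lag_frames),
    stomp_amplitude = stomp_amplitude,
    seed = seed
  ), class = "gait_params")
  validate_gait_params(p)
  p
}

validate_gait_params <- function(p) {
  stopifnot(inherits(p, "gait_params"))
  pos <- c("sample_rate_hz", "n_steps", "stance_frames_mean",
           "cycle_frames_mean", "body_weight_n", "cop_ap_length_cm",
           "cop_ml_excursion_cm", "stomp_amplitude")
  for (f in pos) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1 || !is.finite(p[[f]]) ||
        p[[f]] <= 0)
      stop(sprintf("gait_params: '%s' must be a single positive number", f),
           call. = FALSE)
  }
  for (f in c("stance_frames_sd", "imu_noise_sd", "step_scale_sd")) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1 || !is.finite(p[[f]]) ||
        p[[f]] < 0)
      stop(sprintf("gait_params: '%s' must be a non-negative number", f),
           call. = FALSE)
  }
  if (p$stance_frames_mean >= p$cycle_frames_mean)
    stop("gait_params: stance_frames_mean must be below cycle_frames_mean",
         call. = FALSE)
  invisible(p)
}

#' @export
print.gait_params <- function(x, ...) {
  cat("<gait_params>\n")
  cat(sprintf("  rate %.0f Hz, %d steps, stance %.0f +/- %.0f frames, cycle %.0f frames\n",
              x$sample_rate_hz, x$n_steps, x$stance_frames_mean,
              x$stance_frames_sd, x$cycle_frames_mean))
  cat(sprintf("  COP: AP path %.2f cm, ML excursion %.2f cm; BW %.0f N\n",
              x$cop_ap_length_cm, x$cop_ml_excursion_cm, x$body_weight_n))
  cat(sprintf("  noise %.3f, step jitter %.3f, stomp x%.1f, lag %s\n",
              x$imu_noise_sd, x$step_scale_sd, x$stomp_amplitude,
              if (is.null(x$lag_frames)) "random" else x$lag_frames))
  invisible(x)
}
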