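# Shared fixtures: all synthetic, built in code at test time.

# Small, fast gait parameterization for unit tests (short cycles, few
# steps). The default calibration is exercised separately in the
# acceptance tests.
tiny_params <- function(n_steps = 6, seed = 1, ...) {
  gait_params(n_steps = n_steps, sample_rate_hz = 50,
              stance_frames_mean = 22, stance_frames_sd = 2,
              cycle_frames_mean = 30, seed = seed, ...)
}

# A fast model configuration: the full 64/128/64 architecture but few
# epochs, for plumbing tests that do not assess accuracy.
tiny_config <- function(epochs = 2, seed = 42, ...) {
  model_config(epochs = epochs, batch_size = 32, seed = seed, ...)
}

# Hand-built constant-channel sensor set on n frames.
constant_sensors <- function(n, value = 0) {
  out <- lapply(c("H", "L", "T", "W"), function(s)
    sensor_stream(site = s, sample_rate_hz = 148,
                  channels = matrix(value, n, 6)))
  names(out) <- c("H", "L", "T", "W")
  out
}

# Plantar stream with one rectangular stance pulse [hs, to) of height h.
pulse_plantar <- function(n, hs, to, h = 600, rate = 148) {
  grf <- numeric(n)
  grf[hs:(to - 1)] <- h
  ap <- rep(NA_real_, n)
  ml <- rep(NA_real_, n)
  u <- seq(0, 1, length.out = to - hs)
  ap[hs:(to - 1)] <- 17 * u
  ml[hs:(to - 1)] <- 1.5 * sin(pi * u)
  plantar_stream(sample_rate_hz = rate, grf_n = grf, cop_ap_cm = ap,
                 cop_ml_cm = ml)
}

# Brute-force window counter: independent oracle for build_samples sizing.
count_windows_bruteforce <- function(steps, P, n_frames) {
  total <- 0
  for (k in seq_len(nrow(steps))) {
    for (f in steps$hs_frame[k]:(steps$to_frame[k] - 1)) {
      if (f - P >= 1 && f <= n_frames) total <- total + 1
    }
  }
  total
}
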