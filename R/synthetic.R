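# Synthetic gait simulator: coupled IMU / vertical GRF / COP streams.
#
# All waveforms are phenomenological functions of a latent gait phase
# p in [0, 1) (0 = heel strike): sums of phase-locked Gaussian bumps and
# low-order sinusoids per site and channel. The per-site activity timing
# mirrors stance-phase physiology: the heel is quiet between foot-flat and
# heel-off, the lateral shoe wall is quiet in mid-stance, the toe stays
# dynamic through the whole stance, and the waist sees only low-amplitude
# smooth oscillation. COP and IMU channels are deterministic functions of
# the shared phase times one per-step amplitude multiplier, so the
# IMU-to-COP mapping is learnable by construction.

# One Gaussian bump in phase, wrapped on the unit circle for continuity.
.phase_bump <- function(p, center, width) {
  d <- abs(p - center)
  d <- pmin(d, 1 - d)
  exp(-0.5 * (d / width)^2)
}

# channel recipe: list(bumps = rbind(c(center, width, weight), ...),
#                      sins  = rbind(c(freq, phase, weight), ...),
#                      amp, base)
.eval_channel <- function(p, rc) {
  v <- rep(rc$base %||% 0, length(p))
  if (!is.null(rc$bumps))
    for (i in seq_len(nrow(rc$bumps)))
      v <- v + rc$bumps[i, 3] * .phase_bump(p, rc$bumps[i, 1], rc$bumps[i, 2])
  if (!is.null(rc$sins))
    for (i in seq_len(nrow(rc$sins)))
      v <- v + rc$sins[i, 3] * sin(2 * pi * rc$sins[i, 1] * p + rc$sins[i, 2])
  rc$amp * v
}

.b <- function(...) matrix(c(...), ncol = 3, byrow = TRUE)

# Site recipes. Accelerations in g, angular rates in deg/s. Channel order
# per site: ax, ay, az, gx, gy, gz.
.SITE_RECIPES <- list(
  # Heel: impact burst at heel strike, a heel-off burst near p ~ 0.45 and
  # swing activity around p ~ 0.8; near-baseline through mid-stance.
  H = list(
    list(bumps = .b(0.01, 0.030, 2.2, 0.48, 0.060, 1.0, 0.80, 0.090, 1.1),
         amp = 2.5),
    list(bumps = .b(0.02, 0.030, 1.4, 0.50, 0.050, 0.8, 0.85, 0.070, 0.7),
         amp = 1.2),
    list(bumps = .b(0.01, 0.025, 3.0, 0.45, 0.050, 1.2, 0.78, 0.080, 1.4),
         amp = 3.0, base = 0.33),
    list(bumps = .b(0.47, 0.050, 1.8, 0.82, 0.070, 1.5), amp = 350),
    list(bumps = .b(0.03, 0.030, 1.2, 0.50, 0.060, 1.0, 0.80, 0.080, 0.9),
         amp = 280),
    list(bumps = .b(0.46, 0.070, 0.9, 0.86, 0.050, 0.7), amp = 160)
  ),
  # Lateral shoe wall: early-stance and late-stance bursts plus swing
  # motion; quiet during mid-stance.
  L = list(
    list(bumps = .b(0.05, 0.040, 1.6, 0.58, 0.070, 1.3, 0.82, 0.090, 1.0),
         amp = 2.0),
    list(bumps = .b(0.06, 0.045, 1.0, 0.62, 0.060, 1.1, 0.88, 0.060, 0.6),
         amp = 1.4),
    list(bumps = .b(0.04, 0.035, 2.0, 0.60, 0.065, 1.5, 0.80, 0.080, 1.2),
         amp = 2.2, base = 0.45),
    list(bumps = .b(0.55, 0.080, 1.4, 0.84, 0.060, 1.1), amp = 260),
    list(bumps = .b(0.05, 0.040, 0.9, 0.60, 0.070, 1.3, 0.86, 0.070, 0.8),
         amp = 220),
    list(bumps = .b(0.58, 0.090, 1.0, 0.90, 0.050, 0.6), amp = 140)
  ),
  # Toe: dynamic through the whole stance (metatarsophalangeal flexion keeps
  # it moving even after heel-off) and through swing.
  T = list(
    list(bumps = .b(0.05, 0.050, 1.2, 0.30, 0.090, 0.9, 0.55, 0.080, 1.5,
                    0.80, 0.100, -1.0),
         sins = .b(1, 0.0, 0.30), amp = 2.0),
    list(bumps = .b(0.15, 0.080, 0.7, 0.45, 0.100, 0.8, 0.65, 0.060, 1.2),
         sins = .b(2, 1.0, 0.40), amp = 1.5),
    list(bumps = .b(0.02, 0.040, 1.6, 0.35, 0.100, 1.0, 0.60, 0.070, 1.8),
         sins = .b(1, 2.0, 0.50), amp = 2.5, base = 0.40),
    list(bumps = .b(0.25, 0.100, 0.8, 0.50, 0.100, 1.5, 0.75, 0.080, -1.2),
         sins = .b(1, 0.5, 0.30), amp = 300),
    list(bumps = .b(0.10, 0.060, 0.6, 0.40, 0.120, 1.1, 0.60, 0.080, 2.0),
         sins = .b(2, 0.0, 0.20), amp = 250),
    list(bumps = .b(0.20, 0.090, 0.7, 0.45, 0.120, 1.0, 0.85, 0.060, 0.8),
         sins = .b(1, 1.0, 0.30), amp = 150)
  ),
  # Waist: low-amplitude smooth oscillation at stride and double-stride
  # frequency.
  W = list(
    list(sins = .b(1, 0.0, 1.0, 2, 0.8, 0.5), amp = 0.30),
    list(sins = .b(1, 1.2, 0.8, 2, 0.3, 0.6), amp = 0.25),
    list(sins = .b(2, 0.0, 1.0, 1, 2.1, 0.4), amp = 0.35, base = 1.0),
    list(sins = .b(1, 0.4, 1.0, 2, 1.5, 0.4), amp = 40),
    list(sins = .b(1, 1.8, 0.9, 2, 0.6, 0.5), amp = 35),
    list(sins = .b(2, 0.9, 1.0, 1, 0.2, 0.3), amp = 25)
  )
)

IMU_CHANNELS <- c("ax", "ay", "az", "gx", "gy", "gz")

# Deterministic noiseless IMU matrix (n x 6) for one site over phases p.
.imu_deterministic <- function(site, p, scale = 1) {
  rcs <- .SITE_RECIPES[[site]]
  m <- vapply(rcs, function(rc) .eval_channel(p, rc), numeric(length(p)))
  colnames(m) <- IMU_CHANNELS
  m * scale
}

# Per-channel amplitude used to express noise SD as a signal fraction.
.channel_amps <- function(site) {
  p <- seq(0, 1, length.out = 512)
  apply(abs(.imu_deterministic(site, p)), 2, max)
}

# Normalized double-bump vertical GRF over stance position u in [0, 1].
# The plateau keeps the stance endpoints well above the 10 N / 25 N event
# thresholds so the detected stance equals the generated support.
.grf_shape <- function(u) {
  g1 <- exp(-0.5 * ((u - 0.28) / 0.13)^2)
  g2 <- exp(-0.5 * ((u - 0.75) / 0.13)^2)
  0.12 + 0.95 * (g1 + g2)
}

# Monotone heel-to-toe progression profile, 0 at heel strike, 1 at toe off.
.cop_ap_shape <- function(u) 0.35 * u + 0.65 * (3 * u^2 - 2 * u^3)

# Single smooth lateral arc, zero at both stance ends, peak excursion 1.
.cop_ml_shape <- function(u) sin(pi * u)

#' Generate one synthetic gait cycle
#'
#' Draws one step template: a stance-phase vertical GRF / COP segment
#' followed by a swing phase, plus the matching six-channel IMU series for
#' all four sites, all driven by a shared latent phase. Uses the current R
#' RNG stream (seed with [set.seed()] for reproducibility).
#'
#' @param params A [gait_params()] object.
#' @return A `step_template`: list with `grf` (N), `cop_ap`, `cop_ml` (cm,
#'   `NA` on swing frames), `imu` (site-named list of n x 6 matrices),
#'   `phase`, `stance_frames`, `cycle_frames`, `scale`.
#' @export
generate_step <- function(params = gait_params()) {
  validate_gait_params(params)
  swing <- as.integer(round(params$cycle_frames_mean - params$stance_frames_mean))
  ns <- max(2L, as.integer(round(rnorm(1, params$stance_frames_mean,
                                       params$stance_frames_sd))))
  nc <- ns + swing
  scale <- max(0.1, rnorm(1, 1, params$step_scale_sd))

  p <- (seq_len(nc) - 1) / nc
  u <- (seq_len(ns) - 1) / (ns - 1)

  grf <- numeric(nc)
  grf[seq_len(ns)] <- params$body_weight_n * scale * .grf_shape(u)
  cop_ap <- rep(NA_real_, nc)
  cop_ml <- rep(NA_real_, nc)
  cop_ap[seq_len(ns)] <- params$cop_ap_length_cm * scale * .cop_ap_shape(u)
  cop_ml[seq_len(ns)] <- params$cop_ml_excursion_cm * scale * .cop_ml_shape(u)

  imu <- lapply(SITE_LEVELS, function(site) {
    det <- .imu_deterministic(site, p, scale)
    if (params$imu_noise_sd > 0) {
      amps <- .channel_amps(site)
      det <- det + matrix(rnorm(nc * 6), nc, 6) %*%
        diag(params$imu_noise_sd * amps, 6)
    }
    colnames(det) <- IMU_CHANNELS
    det
  })
  names(imu) <- SITE_LEVELS

  structure(list(grf = grf, cop_ap = cop_ap, cop_ml = cop_ml, imu = imu,
                 phase = p, stance_frames = ns, cycle_frames = nc,
                 scale = scale),
            class = "step_template")
}

# Amplitude of the stomp spike in the heel accelerometer (g) and GRF (N).
.stomp_heights <- function(params) {
  acc_peak <- sqrt(sum(.channel_amps("H")[1:3]^2))
  list(acc = params$stomp_amplitude * acc_peak,
       grf = params$stomp_amplitude * 1.1 * params$body_weight_n)
}

#' Generate a full synthetic walking session
#'
#' Concatenates `n_steps` gait cycles after a pre-gait segment containing a
#' single stomp spike (visible in both the heel accelerometer and the GRF,
#' used downstream for synchronization), applies the inter-stream lag, and
#' records ground-truth step annotations on the plantar clock.
#'
#' @param params A [gait_params()] object. If `params$seed` is set the
#'   session is bitwise reproducible; if `params$lag_frames` is `NULL` the
#'   sensor-vs-plantar lag is drawn uniformly from -30..30 frames.
#' @return A `gait_session`: list with `sensors` (site-named list of
#'   [sensor_stream()]), `plantar` ([plantar_stream()]), `truth_steps`
#'   (data frame `step_idx, hs_frame, to_frame, next_hs_frame`, 1-based,
#'   stance = `[hs_frame, to_frame)`), `lag_frames`, and `params`.
#' @export
#' @examples
#' s <- generate_session(gait_params(n_steps = 3, seed = 7))
#' s$truth_steps
generate_session <- function(params = gait_params()) {
  validate_gait_params(params)
  with_seed(params$seed, {
    rate <- params$sample_rate_hz
    lag <- params$lag_frames %||%
      as.integer(floor(runif(1, -30, 31)))
    if (abs(lag) > 30) lag <- 30L * sign(lag)

    n_pre <- round(2.0 * rate)          # pre-gait segment with the stomp
    n_gap <- round(0.3 * rate)          # quiet gap before the first step
    n_tail <- round(0.5 * rate)

    steps <- replicate(params$n_steps, generate_step(params),
                       simplify = FALSE)
    n_gait <- sum(vapply(steps, `[[`, integer(1), "cycle_frames"))
    n <- n_pre + n_gap + n_gait + n_tail

    grf <- numeric(n)
    cop_ap <- rep(NA_real_, n)
    cop_ml <- rep(NA_real_, n)
    imu <- lapply(SITE_LEVELS, function(s) matrix(0, n, 6,
                                                  dimnames = list(NULL, IMU_CHANNELS)))
    names(imu) <- SITE_LEVELS

    # Baseline sensor noise everywhere (standing still is not exactly zero).
    if (params$imu_noise_sd > 0) {
      for (site in SITE_LEVELS) {
        amps <- .channel_amps(site)
        imu[[site]] <- imu[[site]] + matrix(rnorm(n * 6), n, 6) %*%
          diag(params$imu_noise_sd * amps, 6)
      }
    }

    # Stomp: a single half-sine spike of width 0.05 s centred at 0.5 s.
    w <- max(3L, round(0.05 * rate))
    if (w %% 2 == 0) w <- w + 1L       # odd width -> unambiguous peak frame
    # keep the spike inside the stream even after the largest negative lag
    c0 <- max(round(0.5 * rate), abs(lag) + w + 1L)
    sp <- c0 - (w - 1L) %/% 2L + seq_len(w) - 1L
    shape <- sin(pi * (seq_len(w) - 1) / (w - 1))
    shape[shape < 1e-9] <- 0           # exact zeros at the spike edges
    hts <- .stomp_heights(params)
    grf[sp] <- grf[sp] + hts$grf * shape
    imu$H[sp, "az"] <- imu$H[sp, "az"] + hts$acc * shape

    # Concatenated gait cycles.
    pos <- n_pre + n_gap + 1L
    ann <- data.frame(step_idx = integer(0), hs_frame = integer(0),
                      to_frame = integer(0), next_hs_frame = integer(0))
    for (k in seq_along(steps)) {
      st <- steps[[k]]
      idx <- pos:(pos + st$cycle_frames - 1L)
      grf[idx] <- grf[idx] + st$grf
      cop_ap[idx] <- st$cop_ap
      cop_ml[idx] <- st$cop_ml
      for (site in SITE_LEVELS) imu[[site]][idx, ] <-
          imu[[site]][idx, ] + st$imu[[site]]
      ann <- rbind(ann, data.frame(step_idx = k, hs_frame = pos,
                                   to_frame = pos + st$stance_frames,
                                   next_hs_frame = NA_integer_))
      pos <- pos + st$cycle_frames
    }
    if (nrow(ann) > 1)
      ann$next_hs_frame[-nrow(ann)] <- ann$hs_frame[-1]

    # Apply the inter-stream lag: positive lag delays the sensor streams
    # relative to the plantar stream (events appear `lag` frames later).
    shift_mat <- function(m, lag, site) {
      if (lag == 0) return(m)
      amps <- .channel_amps(site)
      pad <- matrix(rnorm(abs(lag) * 6), abs(lag), 6) %*%
        diag(params$imu_noise_sd * amps, 6)
      colnames(pad) <- IMU_CHANNELS
      if (lag > 0) rbind(pad, m[seq_len(nrow(m) - lag), , drop = FALSE])
      else rbind(m[(abs(lag) + 1):nrow(m), , drop = FALSE], pad)
    }
    sensors <- lapply(SITE_LEVELS, function(site)
      sensor_stream(site = site, sample_rate_hz = rate,
                    channels = shift_mat(imu[[site]], lag, site)))
    names(sensors) <- SITE_LEVELS

    plantar <- plantar_stream(sample_rate_hz = rate, grf_n = grf,
                              cop_ap_cm = cop_ap, cop_ml_cm = cop_ml)

    structure(list(sensors = sensors, plantar = plantar, truth_steps = ann,
                   lag_frames = as.integer(lag), params = params),
              class = "gait_session")
  })
}

#' @export
print.gait_session <- function(x, ...) {
  cat(sprintf("<gait_session> %d steps, %d frames at %.0f Hz, lag %d frames\n",
              nrow(x$truth_steps), length(x$plantar$grf_n),
              x$plantar$sample_rate_hz, x$lag_frames))
  invisible(x)
}

#' Add spurious swing-phase plantar noise
#'
#' Corrupts a random subset of swing frames (vertical GRF exactly zero) with
#' small positive spurious force readings, emulating the pressure-mat noise
#' that must be cleaned before gait-event detection.
#'
#' @param plantar A [plantar_stream()].
#' @param noise_sd SD of the half-normal noise amplitude, in newtons. Zero
#'   leaves the stream untouched.
#' @param prob Per-frame corruption probability on swing frames.
#' @return The corrupted [plantar_stream()].
#' @export
corrupt_swing <- function(plantar, noise_sd, prob = 0.1) {
  stopifnot(inherits(plantar, "plantar_stream"), noise_sd >= 0)
  if (noise_sd == 0) return(plantar)
  swing <- which(plantar$grf_n == 0)
  hit <- swing[runif(length(swing)) < prob]
  plantar$grf_n[hit] <- abs(rnorm(length(hit), 0, noise_sd))
  plantar
}
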