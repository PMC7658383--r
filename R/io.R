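# Data model and CSV I/O for sensor and plantar streams.
#
# Conventions: time is stored as a clock offset t0_s plus a uniform grid at
# sample_rate_hz; frame indices are 1-based and stance slices are half-open
# [hs, to). The swing-phase COP is the sentinel NA, never zero, so that
# downstream code must mask stance explicitly.

SENSOR_COLS <- c("t_s", "ax", "ay", "az", "gx", "gy", "gz")
PLANTAR_COLS <- c("t_s", "grf_n", "cop_ap_cm", "cop_ml_cm")

#' Construct a six-channel IMU stream
#'
#' @param site Sensor site, one of `"H"` (heel), `"L"` (lateral), `"T"`
#'   (toe), `"W"` (waist).
#' @param sample_rate_hz Sampling rate (Hz).
#' @param channels Numeric matrix with 6 columns `ax, ay, az` (g) and
#'   `gx, gy, gz` (deg/s).
#' @param t0_s Clock offset of the first sample, seconds.
#' @return A `sensor_stream` object.
#' @export
sensor_stream <- function(site, sample_rate_hz, channels, t0_s = 0) {
  site <- match.arg(site, SITE_LEVELS)
  channels <- as.matrix(channels)
  if (ncol(channels) != 6)
    stop("sensor_stream: 'channels' must have 6 columns", call. = FALSE)
  if (anyNA(channels) || any(!is.finite(channels)))
    stop("sensor_stream: channels contain missing or non-finite values",
         call. = FALSE)
  if (!is.numeric(sample_rate_hz) || sample_rate_hz <= 0)
    stop("sensor_stream: sample_rate_hz must be positive", call. = FALSE)
  colnames(channels) <- IMU_CHANNELS
  structure(list(site = site, sample_rate_hz = sample_rate_hz,
                 channels = channels, t0_s = t0_s),
            class = "sensor_stream")
}

#' Construct a plantar (insole) stream
#'
#' @param sample_rate_hz Sampling rate (Hz).
#' @param grf_n Vertical ground reaction force, newtons, non-negative.
#' @param cop_ap_cm,cop_ml_cm COP coordinates in cm; `NA` on swing frames.
#' @param t0_s Clock offset of the first sample, seconds.
#' @return A `plantar_stream` object.
#' @export
plantar_stream <- function(sample_rate_hz, grf_n, cop_ap_cm, cop_ml_cm,
                           t0_s = 0) {
  if (any(!is.finite(grf_n)))
    stop("plantar_stream: grf_n contains missing values", call. = FALSE)
  if (any(grf_n < 0))
    stop(sprintf("plantar_stream: negative grf_n at row %d",
                 which(grf_n < 0)[1]), call. = FALSE)
  n <- length(grf_n)
  if (length(cop_ap_cm) != n || length(cop_ml_cm) != n)
    stop("plantar_stream: all series must share the same length",
         call. = FALSE)
  if (!is.numeric(sample_rate_hz) || sample_rate_hz <= 0)
    stop("plantar_stream: sample_rate_hz must be positive", call. = FALSE)
  structure(list(sample_rate_hz = sample_rate_hz, grf_n = grf_n,
                 cop_ap_cm = cop_ap_cm, cop_ml_cm = cop_ml_cm, t0_s = t0_s),
            class = "plantar_stream")
}

#' @export
print.sensor_stream <- function(x, ...) {
  cat(sprintf("<sensor_stream %s> %d frames at %.0f Hz (t0 = %.3f s)\n",
              x$site, nrow(x$channels), x$sample_rate_hz, x$t0_s))
  invisible(x)
}

#' @export
print.plantar_stream <- function(x, ...) {
  cat(sprintf("<plantar_stream> %d frames at %.0f Hz, %d stance frames\n",
              length(x$grf_n), x$sample_rate_hz, sum(x$grf_n > 0)))
  invisible(x)
}

.stream_times <- function(stream) {
  n <- if (inherits(stream, "sensor_stream")) nrow(stream$channels)
       else length(stream$grf_n)
  stream$t0_s + (seq_len(n) - 1) / stream$sample_rate_hz
}

#' Write a stream to CSV
#'
#' Sensor files carry columns `t_s, ax, ay, az, gx, gy, gz`; plantar files
#' carry `t_s, grf_n, cop_ap_cm, cop_ml_cm` (swing COP written as `NA`).
#' Comma-separated, mandatory header, `.` decimal, full double precision.
#'
#' @param stream A [sensor_stream()] or [plantar_stream()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stream <- function(stream, path) {
  t_s <- .stream_times(stream)
  df <- if (inherits(stream, "sensor_stream")) {
    data.frame(t_s = t_s, stream$channels)
  } else if (inherits(stream, "plantar_stream")) {
    data.frame(t_s = t_s, grf_n = stream$grf_n,
               cop_ap_cm = stream$cop_ap_cm, cop_ml_cm = stream$cop_ml_cm)
  } else stop("write_stream: unknown stream type", call. = FALSE)
  write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a stream from CSV
#'
#' Validates the column contract, rejects missing values and non-monotone
#' time, and infers the sampling rate from the median time step.
#'
#' @param path CSV file written in the [write_stream()] schema.
#' @param kind `"sensor"` or `"plantar"`.
#' @param site Sensor site label (required for `kind = "sensor"`).
#' @return A [sensor_stream()] or [plantar_stream()].
#' @export
read_stream <- function(path, kind = c("sensor", "plantar"), site = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path))
    stop(sprintf("read_stream: no such file '%s'", path), call. = FALSE)
  df <- read.csv(path)
  want <- if (kind == "sensor") SENSOR_COLS else PLANTAR_COLS
  if (ncol(df) != length(want) || !identical(names(df), want))
    stop(sprintf(
      "read_stream: '%s' has %d columns (%s); expected %d columns (%s)",
      path, ncol(df), paste(names(df), collapse = ","), length(want),
      paste(want, collapse = ",")), call. = FALSE)
  strict <- setdiff(want, c("cop_ap_cm", "cop_ml_cm"))
  for (cn in strict) {
    bad <- which(!is.finite(df[[cn]]))
    if (length(bad))
      stop(sprintf("read_stream: missing/non-finite value at row %d, column '%s'",
                   bad[1], cn), call. = FALSE)
  }
  dt <- diff(df$t_s)
  if (any(dt <= 0))
    stop(sprintf("read_stream: non-monotone time at row %d",
                 which(dt <= 0)[1] + 1), call. = FALSE)
  rate <- 1 / median(dt)
  if (kind == "sensor") {
    if (is.null(site))
      stop("read_stream: 'site' is required for sensor files", call. = FALSE)
    sensor_stream(site = site, sample_rate_hz = rate,
                  channels = as.matrix(df[, IMU_CHANNELS]), t0_s = df$t_s[1])
  } else {
    plantar_stream(sample_rate_hz = rate, grf_n = df$grf_n,
                   cop_ap_cm = df$cop_ap_cm, cop_ml_cm = df$cop_ml_cm,
                   t0_s = df$t_s[1])
  }
}

#' Write and read step annotations
#'
#' Step annotation files carry `step_idx, hs_frame, to_frame, next_hs_frame`
#' with 1-based frame indices and half-open stance slices `[hs, to)`.
#'
#' @param steps Step annotation data frame.
#' @param path CSV path.
#' @return `path` / the annotation data frame.
#' @export
write_steps <- function(steps, path) {
  write.csv(steps, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_steps
#' @export
read_steps <- function(path) {
  df <- read.csv(path)
  want <- c("step_idx", "hs_frame", "to_frame", "next_hs_frame")
  if (!all(want %in% names(df)))
    stop("read_steps: missing annotation columns", call. = FALSE)
  df[, want]
}

#' Resample a stream onto a uniform grid
#'
#' Linear interpolation of every channel onto a uniform grid at
#' `target_rate_hz` spanning the original time range. The low-frequency
#' content of gait signals makes linear interpolation adequate; first and
#' last samples of monotone ramps are preserved exactly.
#'
#' @param stream A [sensor_stream()] or [plantar_stream()].
#' @param target_rate_hz New sampling rate (Hz), positive.
#' @return A stream of the same class on the new grid.
#' @export
resample_stream <- function(stream, target_rate_hz) {
  if (!is.numeric(target_rate_hz) || target_rate_hz <= 0)
    stop("resample_stream: target_rate_hz must be positive", call. = FALSE)
  t_old <- .stream_times(stream)
  if (length(t_old) < 2)
    stop("resample_stream: need at least 2 samples", call. = FALSE)
  t_new <- seq(t_old[1], t_old[length(t_old)], by = 1 / target_rate_hz)
  interp <- function(v) approx(t_old, v, xout = t_new, method = "linear")$y
  if (inherits(stream, "sensor_stream")) {
    sensor_stream(site = stream$site, sample_rate_hz = target_rate_hz,
                  channels = apply(stream$channels, 2, interp),
                  t0_s = t_new[1])
  } else {
    # COP may contain swing sentinels; interpolate only within stance runs.
    interp_na <- function(v) {
      out <- rep(NA_real_, length(t_new))
      ok <- is.finite(v)
      if (sum(ok) >= 2) {
        y <- approx(t_old[ok], v[ok], xout = t_new, method = "linear")$y
        inside <- vapply(t_new, function(tt) {
          i <- findInterval(tt, t_old)
          i >= 1 && i < length(v) && ok[i] && ok[i + 1]
        }, logical(1))
        out[inside] <- y[inside]
      }
      out
    }
    plantar_stream(sample_rate_hz = target_rate_hz,
                   grf_n = pmax(0, interp(stream$grf_n)),
                   cop_ap_cm = interp_na(stream$cop_ap_cm),
                   cop_ml_cm = interp_na(stream$cop_ml_cm),
                   t0_s = t_new[1])
  }
}
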