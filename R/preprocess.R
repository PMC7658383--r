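# Synchronization, swing-noise cleaning, gait-event detection, step
# trimming and train/test splitting.

#' Synchronize sensor streams to the plantar clock
#'
#' Locates the first prominent peak in the heel accelerometer magnitude and
#' in the vertical GRF inside the pre-gait search window (both are produced
#' by the stomp at the start of a session) and shifts every sensor stream so
#' the two peaks coincide.
#'
#' @param sensors Site-named list of [sensor_stream()]; must contain `"H"`.
#' @param plantar A [plantar_stream()].
#' @param search_s Length of the search window from the start, seconds.
#' @param min_grf_peak_n,min_acc_peak_g Minimum peak heights; below them the
#'   stomp is considered absent and synchronization fails.
#' @return List with shifted `sensors`, untouched `plantar`, and the
#'   recovered `lag_frames` (positive = sensors lagged the plantar stream).
#' @export
synchronize <- function(sensors, plantar, search_s = 2.5,
                        min_grf_peak_n = 50, min_acc_peak_g = 1) {
  if (!("H" %in% names(sensors)))
    stop("synchronize: heel sensor 'H' is required", call. = FALSE)
  rate <- plantar$sample_rate_hz
  wp <- seq_len(min(length(plantar$grf_n), round(search_s * rate)))
  if (max(plantar$grf_n[wp]) < min_grf_peak_n)
    stop("synchronize: no GRF peak above prominence threshold in the search window",
         call. = FALSE)
  i_grf <- which.max(plantar$grf_n[wp])

  accmag <- sqrt(rowSums(sensors$H$channels[, 1:3, drop = FALSE]^2))
  ws <- seq_len(min(length(accmag), round(search_s * rate)))
  if (max(accmag[ws]) < min_acc_peak_g)
    stop("synchronize: no heel acceleration peak above prominence threshold",
         call. = FALSE)
  i_acc <- which.max(accmag[ws])

  lag <- as.integer(i_acc - i_grf)
  shifted <- lapply(sensors, function(s) shift_sensor(s, -lag))
  list(sensors = shifted, plantar = plantar, lag_frames = lag)
}

# Shift a sensor stream by `by` frames (positive = delay), replicating edge
# frames to keep the length unchanged.
shift_sensor <- function(stream, by) {
  if (by == 0) return(stream)
  m <- stream$channels
  n <- nrow(m)
  k <- min(abs(by), n)
  m2 <- if (by > 0) {
    rbind(m[rep(1, k), , drop = FALSE], m[seq_len(n - k), , drop = FALSE])
  } else {
    rbind(m[(k + 1):n, , drop = FALSE], m[rep(n, k), , drop = FALSE])
  }
  sensor_stream(site = stream$site, sample_rate_hz = stream$sample_rate_hz,
                channels = m2, t0_s = stream$t0_s)
}

#' Eliminate swing-phase plantar noise
#'
#' Frames whose vertical GRF is below `threshold_n` are treated as airborne
#' noise: their GRF is set to 0 and their COP to the swing sentinel (`NA`).
#' Frames at or above the threshold are untouched.
#'
#' @param plantar A [plantar_stream()].
#' @param threshold_n Force threshold in newtons, positive.
#' @return The cleaned [plantar_stream()].
#' @export
clean_swing_noise <- function(plantar, threshold_n = 10) {
  stopifnot(inherits(plantar, "plantar_stream"))
  if (!is.numeric(threshold_n) || threshold_n <= 0)
    stop("clean_swing_noise: threshold_n must be positive", call. = FALSE)
  low <- plantar$grf_n < threshold_n
  plantar$grf_n[low] <- 0
  plantar$cop_ap_cm[low] <- NA_real_
  plantar$cop_ml_cm[low] <- NA_real_
  plantar
}

#' Detect gait events from vertical GRF thresholds
#'
#' Heel strike is the first frame of each contiguous supra-zero GRF epoch at
#' which the force reaches `hs_threshold_n`; toe off is the first frame
#' after that epoch's GRF maximum at which the force falls below
#' `to_threshold_n`. The rising 10 N crossing matches heel-strike loading
#' and the falling 25 N crossing matches push-off unloading. Epochs whose
#' stance is shorter than `min_stance_s` (artifacts such as the
#' synchronization stomp) are discarded.
#'
#' @param plantar A cleaned [plantar_stream()] (see [clean_swing_noise()]).
#' @param hs_threshold_n,to_threshold_n Event thresholds in newtons.
#' @param min_stance_s Minimum stance duration in seconds.
#' @param ignore_before Optional frame index; epochs starting before it are
#'   dropped (e.g. the stomp region).
#' @return Data frame `step_idx, hs_frame, to_frame, next_hs_frame` with
#'   1-based indices and half-open stance `[hs_frame, to_frame)`; zero rows
#'   when no contact is found.
#' @export
detect_gait_events <- function(plantar, hs_threshold_n = 10,
                               to_threshold_n = 25, min_stance_s = 0.3,
                               ignore_before = NULL) {
  stopifnot(inherits(plantar, "plantar_stream"))
  g <- plantar$grf_n
  rate <- plantar$sample_rate_hz
  r <- rle(g > 0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  hs <- integer(0); to <- integer(0)
  for (k in which(r$values)) {
    lo <- starts[k]; hi <- ends[k]
    seg <- g[lo:hi]
    i_hs <- which(seg >= hs_threshold_n)[1]
    if (is.na(i_hs)) next
    i_pk <- i_hs - 1 + which.max(seg[i_hs:length(seg)])
    after <- which(seg[-seq_len(i_pk)] < to_threshold_n)
    i_to <- if (length(after)) i_pk + after[1] else length(seg) + 1
    h <- lo + i_hs - 1L
    t <- lo + i_to - 1L
    if (!is.null(ignore_before) && h < ignore_before) next
    if ((t - h) / rate < min_stance_s) next
    hs <- c(hs, h); to <- c(to, t)
  }
  n <- length(hs)
  data.frame(step_idx = seq_len(n), hs_frame = hs, to_frame = to,
             next_hs_frame = if (n) c(hs[-1], NA_integer_) else integer(0))
}

#' Trim edge steps of each trip
#'
#' Walking trials recorded as back-and-forth trips start and end with
#' acceleration/deceleration steps that are not representative of steady
#' gait; the first and last `n_edge` steps of each trip are removed.
#'
#' @param steps Step annotation data frame (ordered by `hs_frame`).
#' @param trip_boundaries Frame indices at which a new trip starts; an empty
#'   vector treats the whole recording as one trip.
#' @param n_edge Number of steps to drop at each end of every trip.
#' @return The retained steps. Trips with `<= 2 * n_edge` steps contribute
#'   nothing and raise a warning.
#' @export
trim_steps <- function(steps, trip_boundaries = integer(0), n_edge = 3) {
  if (nrow(steps) == 0) return(steps)
  stopifnot(!is.unsorted(steps$hs_frame))
  trip <- findInterval(steps$hs_frame, sort(trip_boundaries)) + 1L
  keep <- logical(nrow(steps))
  for (tr in unique(trip)) {
    idx <- which(trip == tr)
    if (length(idx) <= 2 * n_edge) {
      warning(sprintf("trim_steps: trip %d has only %d steps; all dropped",
                      tr, length(idx)), call. = FALSE)
      next
    }
    keep[idx[(n_edge + 1):(length(idx) - n_edge)]] <- TRUE
  }
  steps[keep, , drop = FALSE]
}

#' Randomly split steps into training and test sets
#'
#' Uniform partition without replacement at the step level (not the frame
#' level), so that overlapping lookback windows never straddle the
#' train/test boundary.
#'
#' @param steps Step annotation data frame (>= 2 rows).
#' @param fraction Training fraction in (0, 1); `round(fraction * n)` steps
#'   are assigned to training.
#' @param seed Optional integer seed for reproducibility.
#' @return A `split_plan`: list with `train_steps`, `test_steps` (values of
#'   `step_idx`), `fraction`, `seed`.
#' @export
split_steps <- function(steps, fraction = 0.7, seed = NULL) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    stop("split_steps: fraction must be in (0, 1)", call. = FALSE)
  ids <- steps$step_idx
  n <- length(ids)
  if (n < 2) stop("split_steps: need at least 2 steps", call. = FALSE)
  n_train <- round(fraction * n)
  train <- with_seed(seed, sort(sample(ids, n_train)))
  structure(list(train_steps = train, test_steps = setdiff(ids, train),
                 fraction = fraction, seed = seed),
            class = "split_plan")
}

#' Pressure-weighted COP centroid
#'
#' Standard centroid of a plantar pressure grid: each axis coordinate is the
#' pressure-weighted mean of the cell positions. Useful for deriving COP
#' when a raw sensel grid, rather than a vendor COP channel, is available.
#'
#' @param pressures Non-negative cell forces (any shape; flattened).
#' @param coords_ap_cm,coords_ml_cm Cell positions, same length as
#'   `pressures`.
#' @return Named vector `c(cop_ap_cm, cop_ml_cm)`.
#' @export
compute_cop_centroid <- function(pressures, coords_ap_cm, coords_ml_cm) {
  p <- as.numeric(pressures)
  if (length(coords_ap_cm) != length(p) || length(coords_ml_cm) != length(p))
    stop("compute_cop_centroid: coordinate/pressure lengths differ",
         call. = FALSE)
  tot <- sum(p)
  if (tot <= 0)
    stop("compute_cop_centroid: undefined COP, all cells are zero",
         call. = FALSE)
  c(cop_ap_cm = sum(p * coords_ap_cm) / tot,
    cop_ml_cm = sum(p * coords_ml_cm) / tot)
}
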