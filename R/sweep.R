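# Sensor-placement sweep: run the full pipeline for every non-empty subset
# of the heel/lateral/toe/waist sites and report per-combination accuracy.

#' Enumerate sensor-site combinations
#'
#' All non-empty subsets of the universe, ordered by subset size then
#' lexical site order. For the four-site universe this yields the 15
#' combinations H, L, T, W, H+L, H+T, H+W, L+T, L+W, T+W, H+L+T, H+L+W,
#' H+T+W, L+T+W, H+L+T+W.
#'
#' @param universe Character vector of site labels.
#' @return List of character vectors (each a site subset).
#' @export
enumerate_combinations <- function(universe = SITE_LEVELS) {
  universe <- sort(unique(universe))
  if (length(universe) == 0)
    stop("enumerate_combinations: empty universe", call. = FALSE)
  out <- list()
  for (k in seq_along(universe)) {
    cmb <- utils::combn(universe, k, simplify = FALSE)
    cmb <- cmb[order(vapply(cmb, paste, "", collapse = "+"))]
    out <- c(out, cmb)
  }
  out
}

#' Label a site subset
#' @param sites Character vector of sites.
#' @return Label such as `"H+T"`.
#' @export
combo_label <- function(sites) paste(sites, collapse = "+")

# Preprocess one session up to the split: synchronize, clean, detect,
# optionally trim, split, and compute the lookback period.
.prepare_session <- function(session, split_seed = NULL, fraction = 0.7,
                             clean_threshold_n = 10, hs_threshold_n = 10,
                             to_threshold_n = 25, edge_trim = 0,
                             lookback = NULL) {
  sync <- synchronize(session$sensors, session$plantar)
  plantar <- clean_swing_noise(sync$plantar, clean_threshold_n)
  steps <- detect_gait_events(plantar, hs_threshold_n, to_threshold_n)
  if (edge_trim > 0) steps <- trim_steps(steps, n_edge = edge_trim)
  split <- split_steps(steps, fraction = fraction, seed = split_seed)
  train <- steps[steps$step_idx %in% split$train_steps, , drop = FALSE]
  P <- lookback %||% mean_step_period(train)
  list(sensors = sync$sensors, plantar = plantar, steps = steps,
       split = split, lookback = P, lag_frames = sync$lag_frames)
}

# Train on the training steps of prepared data and evaluate every test
# step; returns per-step metric rows plus the fitted model.
.fit_and_score <- function(prep, sites, direction, config) {
  spec <- window_spec(sites, direction, prep$lookback)
  smp <- build_samples(prep$sensors, prep$plantar, prep$steps, spec)
  .fit_and_score_samples(smp, prep, sites, direction, config)
}

.fit_and_score_samples <- function(smp, prep, sites, direction, config) {
  train_smp <- standardize_samples(
    subset_samples(smp, step_ids = prep$split$train_steps))
  model <- train_copnet(train_smp, config)

  cop <- if (direction == "AP") prep$plantar$cop_ap_cm
         else prep$plantar$cop_ml_cm
  rows <- list()
  for (sid in prep$split$test_steps) {
    st <- prep$steps[prep$steps$step_idx == sid, ]
    test_smp <- subset_samples(smp, step_ids = sid)
    pred <- predict(model, test_smp)
    meas <- cop[test_smp$frame_idx]
    rows[[length(rows) + 1]] <- data.frame(
      sites = combo_label(sites), direction = direction,
      step_idx = sid, n_frames = length(meas),
      nrmse = nrmse(meas, pred), jaccard = jaccard_index(meas, pred),
      feature_dim = length(sites) * 6L)
  }
  list(per_step = do.call(rbind, rows), model = model)
}

#' Run the pipeline for one sensor combination
#'
#' Synchronizes the session, cleans swing noise, detects gait events with
#' the 10 N / 25 N thresholds, splits steps 70/30, sets the lookback to the
#' mean training cycle length, trains the LSTM and evaluates NRMSE and the
#' Jaccard index on every test step.
#'
#' @param session A `gait_session` (see [generate_session()]).
#' @param sites Sensor subset, e.g. `c("T")` or `c("H", "T")`.
#' @param direction `"AP"` or `"ML"`.
#' @param config A [model_config()].
#' @param split_seed Seed for the 70/30 step split.
#' @param fraction Training fraction.
#' @param edge_trim Steps to drop at each end of the recording (0 keeps
#'   all detected steps).
#' @param lookback Override the lookback period in frames (`NULL` = mean
#'   training cycle length).
#' @return List with `per_step` (one metric row per test step), `summary`
#'   (aggregated mean/SD), `model`, `split`, `lookback`.
#' @export
run_pipeline <- function(session, sites, direction = c("AP", "ML"),
                         config = model_config(), split_seed = NULL,
                         fraction = 0.7, edge_trim = 0, lookback = NULL) {
  direction <- match.arg(direction)
  prep <- .prepare_session(session, split_seed = split_seed,
                           fraction = fraction, edge_trim = edge_trim,
                           lookback = lookback)
  res <- .fit_and_score(prep, sites, direction, config)
  long <- data.frame(
    sites = res$per_step$sites, direction = res$per_step$direction,
    metric = rep(c("nrmse", "jaccard"), each = nrow(res$per_step)),
    value = c(res$per_step$nrmse, res$per_step$jaccard))
  list(per_step = res$per_step, summary = aggregate_metrics(long),
       model = res$model, split = prep$split, lookback = prep$lookback)
}

#' Sweep all sensor combinations
#'
#' Runs the full pipeline for every combination in `combos` and every
#' requested direction, sharing one train/test split and one lookback
#' period across combinations (so placement effects are compared on
#' identical steps). Windows are built once for the full site universe and
#' feature columns are subset per combination.
#'
#' @param session A `gait_session`.
#' @param combos List of site subsets, default [enumerate_combinations()].
#' @param directions Directions to evaluate.
#' @param config A [model_config()].
#' @param split_seed Seed for the shared 70/30 split.
#' @param fraction Training fraction.
#' @param edge_trim Steps to drop at each end of the recording.
#' @param output_dir Optional directory; when given, writes `report.csv`,
#'   `per_step.csv` and one measured-vs-predicted overlay PNG per
#'   combination and direction.
#' @param verbose Log each stage.
#' @return List with `report` (one row per combination x direction:
#'   mean/SD NRMSE and Jaccard), `per_step` (archive of every test-step
#'   evaluation), `split`, `lookback`.
#' @export
run_sweep <- function(session, combos = enumerate_combinations(),
                      directions = c("AP", "ML"), config = model_config(),
                      split_seed = NULL, fraction = 0.7, edge_trim = 0,
                      output_dir = NULL, verbose = FALSE) {
  prep <- .prepare_session(session, split_seed = split_seed,
                           fraction = fraction, edge_trim = edge_trim)
  universe <- sort(unique(unlist(combos)))
  per_step <- list()
  if (!is.null(output_dir))
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)

  for (direction in directions) {
    full_spec <- window_spec(universe, direction, prep$lookback)
    full_smp <- build_samples(prep$sensors, prep$plantar, prep$steps,
                              full_spec)
    for (sites in combos) {
      lab <- combo_label(sites)
      if (verbose)
        message(sprintf("[sweep] %s %s (split seed %s, P = %d)", lab,
                        direction, split_seed %||% "<none>", prep$lookback))
      res <- tryCatch({
        smp <- subset_samples(full_smp, sites = sites)
        .fit_and_score_samples(smp, prep, sites, direction, config)
      }, error = function(e) {
        message(sprintf("[sweep] %s %s failed: %s", lab, direction,
                        conditionMessage(e)))
        NULL
      })
      if (is.null(res)) next
      per_step[[length(per_step) + 1]] <- res$per_step
      if (!is.null(output_dir)) {
        cop <- if (direction == "AP") prep$plantar$cop_ap_cm
               else prep$plantar$cop_ml_cm
        sid <- prep$split$test_steps[1]
        st <- prep$steps[prep$steps$step_idx == sid, ]
        pred <- predict_trajectory(res$model, prep$sensors, st)
        f <- st$hs_frame:(st$to_frame - 1L)
        f <- f[f - prep$lookback >= 1]
        grDevices::png(file.path(output_dir,
                                 sprintf("overlay_%s_%s.png",
                                         gsub("\\+", "", lab), direction)),
                       width = 600, height = 400)
        plot_cop_overlay(cop[f], pred,
                         main = sprintf("%s, %s", lab, direction))
        grDevices::dev.off()
      }
    }
  }
  per_step <- do.call(rbind, per_step)
  long <- data.frame(
    sites = rep(per_step$sites, 2), direction = rep(per_step$direction, 2),
    metric = rep(c("nrmse", "jaccard"), each = nrow(per_step)),
    value = c(per_step$nrmse, per_step$jaccard))
  agg <- aggregate_metrics(long)
  report <- .widen_report(agg, per_step)
  if (!is.null(output_dir)) {
    write.csv(report, file.path(output_dir, "report.csv"),
              row.names = FALSE)
    write.csv(per_step, file.path(output_dir, "per_step.csv"),
              row.names = FALSE)
    if (requireNamespace("jsonlite", quietly = TRUE))
      jsonlite::write_json(report, file.path(output_dir, "report.json"),
                           dataframe = "rows", digits = NA)
  }
  list(report = report, per_step = per_step, split = prep$split,
       lookback = prep$lookback)
}

.widen_report <- function(agg, per_step) {
  keys <- unique(agg[, c("sites", "direction")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    s <- keys$sites[i]; d <- keys$direction[i]
    g <- function(m, col) {
      r <- agg[agg$sites == s & agg$direction == d & agg$metric == m, ]
      if (nrow(r)) r[[col]] else NA_real_
    }
    data.frame(sites = s, direction = d,
               nrmse_mean = g("nrmse", "mean"), nrmse_sd = g("nrmse", "sd"),
               jaccard_mean = g("jaccard", "mean"),
               jaccard_sd = g("jaccard", "sd"),
               n_steps = g("nrmse", "n"),
               feature_dim = per_step$feature_dim[
                 match(s, per_step$sites)])
  })
  out <- do.call(rbind, rows)
  sz <- lengths(strsplit(out$sites, "+", fixed = TRUE))
  out <- out[order(out$direction, sz, out$sites), ]
  rownames(out) <- NULL
  out
}

#' Plot a measured-vs-predicted COP overlay
#'
#' @param measured,predicted COP series over one stance phase (cm).
#' @param main Plot title.
#' @export
plot_cop_overlay <- function(measured, predicted, main = "COP trajectory") {
  n <- length(measured)
  graphics::plot(seq_len(n), measured, type = "l", col = "black", lwd = 2,
                 xlab = "stance frame", ylab = "COP (cm)", main = main,
                 ylim = range(c(measured, predicted)))
  graphics::lines(seq_len(length(predicted)), predicted, col = "red",
                  lty = 2, lwd = 2)
  graphics::legend("topleft", legend = c("measured", "predicted"),
                   col = c("black", "red"), lty = c(1, 2), bty = "n")
}
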