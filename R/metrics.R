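# Evaluation statistics: range-normalized RMSE and the area-based Jaccard
# profile-similarity index, plus per-combination aggregation.

.check_pair <- function(measured, predicted) {
  if (length(measured) != length(predicted))
    stop("curve pair: measured and predicted lengths differ", call. = FALSE)
  if (length(measured) < 2)
    stop("curve pair: need at least 2 samples", call. = FALSE)
  if (any(!is.finite(measured)) || any(!is.finite(predicted)))
    stop("curve pair: non-finite values", call. = FALSE)
}

#' Range-normalized root-mean-square error
#'
#' `100 * RMSE(measured, predicted) / (max(measured) - min(measured))`,
#' with N equal to the pair's actual sample count. Larger values indicate
#' larger deviation between ground truth and prediction. The statistic is
#' invariant under a common affine rescaling of both curves.
#'
#' @param measured,predicted COP series (cm) over one stance phase, equal
#'   lengths.
#' @return NRMSE in percent.
#' @export
nrmse <- function(measured, predicted) {
  .check_pair(measured, predicted)
  rng <- max(measured) - min(measured)
  if (rng == 0)
    stop("nrmse: measured curve has zero range, normalization undefined",
         call. = FALSE)
  100 * sqrt(mean((measured - predicted)^2)) / rng
}

#' Area-based Jaccard similarity of two COP curves
#'
#' Both curves are first shifted so that their origins (first samples) are
#' zero, then offset together by their common minimum so both are
#' non-negative (this preserves the inter-curve geometry while making the
#' area interpretation well-defined for curves that go negative, as ML COP
#' does). The index is the trapezoidal area under the pointwise minimum
#' divided by the area under the pointwise maximum. Identical curves give
#' 1; a curve and its doubling give 0.5; two identically-zero curves give 1
#' by convention.
#'
#' @param measured,predicted COP series (cm) over one stance phase, equal
#'   lengths on a shared uniform grid.
#' @return Similarity in `[0, 1]`.
#' @export
jaccard_index <- function(measured, predicted) {
  .check_pair(measured, predicted)
  a <- measured - measured[1]
  b <- predicted - predicted[1]
  off <- min(c(a, b))
  a <- a - off
  b <- b - off
  x <- seq_along(a)
  inter <- pracma::trapz(x, pmin(a, b))
  union <- pracma::trapz(x, pmax(a, b))
  if (union == 0) return(1)
  inter / union
}

#' Aggregate per-step metric values by sensor combination
#'
#' @param values Data frame with columns `sites` (combination label),
#'   `direction`, `metric`, `value` — one row per evaluated test step.
#' @return Data frame `sites, direction, metric, mean, sd, n`, ordered by
#'   subset size then lexical site order; single-value groups report
#'   `sd = 0` with `n = 1`. Empty groups are excluded.
#' @export
aggregate_metrics <- function(values) {
  stopifnot(all(c("sites", "direction", "metric", "value") %in%
                  names(values)))
  values <- values[is.finite(values$value), , drop = FALSE]
  key <- interaction(values$sites, values$direction, values$metric,
                     drop = TRUE)
  rows <- lapply(split(values, key), function(g) {
    data.frame(sites = g$sites[1], direction = g$direction[1],
               metric = g$metric[1], mean = mean(g$value),
               sd = if (nrow(g) > 1) sd(g$value) else 0, n = nrow(g))
  })
  out <- do.call(rbind, rows)
  sz <- lengths(strsplit(out$sites, "+", fixed = TRUE))
  out <- out[order(out$direction, out$metric, sz, out$sites), ]
  rownames(out) <- NULL
  out
}
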