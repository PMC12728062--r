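#' Histogram plug-in mutual information
#'
#' Mutual information I(x; y) in bits from an `n_bins` x `n_bins`
#' equal-width histogram. Non-negative by construction; degenerate
#' (constant) inputs return 0 with a warning.
#'
#' @param x,y numeric vectors of equal length (>= 100 recommended).
#' @param n_bins number of bins per axis, default 16.
#' @return mutual information in bits.
#' @export
mutual_info <- function(x, y, n_bins = 16) {
  stopifnot(length(x) == length(y))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input; mutual information is 0")
    return(0)
  }
  bx <- cut(x, breaks = seq(min(x), max(x), length.out = n_bins + 1),
            include.lowest = TRUE, labels = FALSE)
  by <- cut(y, breaks = seq(min(y), max(y), length.out = n_bins + 1),
            include.lowest = TRUE, labels = FALSE)
  joint <- table(bx, by) / length(x)
  px <- rowSums(joint)
  py <- colSums(joint)
  outer_p <- outer(px, py)
  nz <- joint > 0
  sum(joint[nz] * log2(joint[nz] / outer_p[nz]))
}

#' Task-level features from a trial log
#'
#' Fitts index of difficulty `ID = log2(D/W + 1)` and throughput
#' `TP = ID / T` per trial, plus aggregates: success rate, mean completion
#' time and the inter-trial coefficient of variation of completion time.
#'
#' @param trials non-empty list of [trial_spec()].
#' @return list with `per_trial` (data frame `trial_id, ID, TP, T,
#'   success`) and `aggregate` (named vector `fitts_ID, fitts_TP,
#'   success_rate, completion_time, inter_trial_CV`).
#' @export
task_features <- function(trials) {
  if (length(trials) == 0) stop("trial list must be non-empty")
  W <- vapply(trials, function(t) t$width_W, numeric(1))
  if (any(W <= 0)) stop("target width must be positive")
  D <- vapply(trials, function(t) t$distance_D, numeric(1))
  T <- vapply(trials, function(t) t$duration_T, numeric(1))
  succ <- vapply(trials, function(t) isTRUE(t$success), logical(1))
  id <- log2(D / W + 1)
  tp <- id / T
  per_trial <- data.frame(
    trial_id = vapply(trials, function(t) t$trial_id, numeric(1)),
    ID = id, TP = tp, T = T, success = succ)
  agg <- c(fitts_ID = mean(id),
           fitts_TP = mean(tp),
           success_rate = mean(succ),
           completion_time = mean(T),
           inter_trial_CV = stats::sd(T) / mean(T))
  list(per_trial = per_trial, aggregate = agg)
}
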