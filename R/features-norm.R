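#' Fit an individualized feature baseline
#'
#' Per-feature mean/SD, median/IQR, a ratio reference (mean over the
#' calibration rows, typically the first three sessions) and an
#' exponential-moving-average state for adaptive drift tracking.
#'
#' @param X numeric matrix of calibration feature rows (rows = windows or
#'   segments, named columns).
#' @param alpha EMA rate in `[0.01, 0.05]` typically; default 0.05.
#' @return object of class `baseline_ref`.
#' @export
fit_baseline <- function(X, alpha = 0.05) {
  X <- as.matrix(X)
  stopifnot(!is.null(colnames(X)), alpha > 0, alpha <= 1)
  structure(list(
    mu = colMeans(X, na.rm = TRUE),
    sigma = apply(X, 2, stats::sd, na.rm = TRUE),
    median = apply(X, 2, stats::median, na.rm = TRUE),
    iqr = apply(X, 2, stats::IQR, na.rm = TRUE),
    ratio_ref = colMeans(X, na.rm = TRUE),
    ema = colMeans(X, na.rm = TRUE),
    alpha = alpha),
    class = "baseline_ref")
}

#' Exponential moving average baseline update
#'
#' `mu_t = alpha * x_t + (1 - alpha) * mu_{t-1}` per feature.
#'
#' @param ref a [fit_baseline()] object.
#' @param x named numeric vector of new feature values.
#' @return updated `baseline_ref`.
#' @export
ema_update <- function(ref, x) {
  stopifnot(inherits(ref, "baseline_ref"))
  nm <- intersect(names(x), names(ref$ema))
  ref$ema[nm] <- ref$alpha * x[nm] + (1 - ref$alpha) * ref$ema[nm]
  ref
}

#' Normalize features against an individualized baseline
#'
#' Modes: `zscore` `(x - mu)/sigma`, `robust` `(x - median)/IQR`, `ratio`
#' `x / ratio_ref`. Features whose scale statistic is zero are masked (NA).
#'
#' @param x named numeric vector of raw features.
#' @param ref a [fit_baseline()] object.
#' @param mode `"zscore"`, `"robust"` or `"ratio"`.
#' @return named numeric vector of normalized features.
#' @export
normalize_features <- function(x, ref, mode = c("zscore", "robust", "ratio")) {
  mode <- match.arg(mode)
  stopifnot(inherits(ref, "baseline_ref"))
  nm <- names(x)
  out <- switch(mode,
    zscore = (x - ref$mu[nm]) / ifelse(ref$sigma[nm] == 0, NA, ref$sigma[nm]),
    robust = (x - ref$median[nm]) / ifelse(ref$iqr[nm] == 0, NA, ref$iqr[nm]),
    ratio = x / ifelse(ref$ratio_ref[nm] == 0, NA, ref$ratio_ref[nm]))
  names(out) <- nm
  out
}

#' Invert [normalize_features()] (zscore and ratio modes)
#'
#' @param z named numeric vector of normalized features.
#' @inheritParams normalize_features
#' @return named numeric vector on the raw scale.
#' @export
denormalize_features <- function(z, ref, mode = c("zscore", "robust", "ratio")) {
  mode <- match.arg(mode)
  nm <- names(z)
  switch(mode,
    zscore = z * ref$sigma[nm] + ref$mu[nm],
    robust = z * ref$iqr[nm] + ref$median[nm],
    ratio = z * ref$ratio_ref[nm])
}

#' Feature selection / reduction
#'
#' Online mode: drop near-zero-variance columns, rank the rest by mutual
#' information with the label, prune redundant pairs (|Pearson r| > 0.95,
#' keeping the higher-MI member; ties broken by column order) and keep at
#' most `budget` features. Offline mode: PCA retaining at least
#' `var_retain` cumulative variance.
#'
#' @param X numeric feature matrix (no all-NA columns).
#' @param y numeric label vector (online mode).
#' @param budget maximum number of online features (default 30, typical
#'   range 20-40).
#' @param mode `"online"` or `"offline"`.
#' @param var_retain cumulative variance to retain offline, default 0.95.
#' @param cor_prune redundancy pruning threshold on |r|, default 0.95.
#' @return online: integer vector of selected column indices. Offline: the
#'   `prcomp` object truncated to the retained components (element
#'   `n_components` added).
#' @export
select_features <- function(X, y = NULL, budget = 30,
                            mode = c("online", "offline"),
                            var_retain = 0.95, cor_prune = 0.95) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  if (budget < 1) stop("budget must be >= 1")
  if (mode == "offline") {
    pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
    cv <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
    k <- which(cv >= var_retain)[1]
    pc$rotation <- pc$rotation[, seq_len(k), drop = FALSE]
    pc$x <- pc$x[, seq_len(k), drop = FALSE]
    pc$n_components <- k
    return(pc)
  }
  stopifnot(!is.null(y), nrow(X) == length(y))
  v <- apply(X, 2, stats::var)
  cand <- which(v > 1e-10 * max(v, 1e-300))
  if (length(cand) == 0) stop("no features with non-zero variance")
  mi <- vapply(cand, function(j)
    suppressWarnings(mutual_info(X[, j], y, n_bins = 8)), numeric(1))
  ord <- cand[order(-mi, cand)]          # MI desc, index order on ties
  selected <- integer(0)
  for (j in ord) {
    if (length(selected) >= budget) break
    if (length(selected) > 0) {
      r <- suppressWarnings(
        abs(stats::cor(X[, j], X[, selected, drop = FALSE])))
      if (any(r > cor_prune, na.rm = TRUE)) next
    }
    selected <- c(selected, j)
  }
  sort(selected)
}
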