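#' Linear interpolation of clinical-anchor proxies
#'
#' Interpolates the clinical scale between its baseline and final anchors
#' under an assumed monotone recovery:
#' `FMA_s = FMA_0 + (t_s / T) (FMA_T - FMA_0)`.
#'
#' @param fma_0 baseline anchor score.
#' @param fma_T final anchor score.
#' @param T total course length (sessions); must be > 0.
#' @param t_s session index/time in `[0, T]` (vectorized).
#' @return interpolated score(s).
#' @export
interpolate_proxy <- function(fma_0, fma_T, T, t_s) {
  if (T == 0) stop("course length T must be > 0")
  if (any(t_s < 0 | t_s > T)) stop("t_s must lie in [0, T]")
  fma_0 + t_s / T * (fma_T - fma_0)
}

#' Biomechanically anchored window proxy
#'
#' Refines the interpolated session score with the window's within-session
#' feature deviation: `proxy = clip(FMA_s (1 + kappa * z_bar), 0, 66)`
#' where `z_bar` is the mean within-session z-score of the biomechanical
#' features (ROMn, smoothness deficit, RMS). With `kappa = 0` (or a
#' missing `z_bar`) this reduces to the interpolated value, preserving
#' inter-session monotonicity of session means.
#'
#' @param fma_s interpolated session score.
#' @param z_bar mean within-session feature z-score of the window
#'   (vectorized; NA falls back to 0).
#' @param kappa anchoring gain, default 0.05.
#' @return refined proxy score(s) in `[0, 66]`.
#' @export
anchor_proxy <- function(fma_s, z_bar, kappa = 0.05) {
  z_bar[is.na(z_bar)] <- 0
  pmin(pmax(fma_s * (1 + kappa * z_bar), 0), 66)
}

#' Assign proxy-label sources at fixed proportions
#'
#' Stratified assignment of windows to label sources (interpolated /
#' anchored / expert) at the given data fractions — sources are blended by
#' data share, not by value averaging. Counts use largest-remainder
#' rounding so each proportion is within one window of its target;
#' assignment order is randomized from the current RNG state.
#'
#' @param n number of windows.
#' @param weights source fractions summing to 1, default
#'   `c(0.80, 0.15, 0.05)`.
#' @param sources source names.
#' @return character vector of length `n` with the source of each window.
#' @export
blend_labels <- function(n, weights = c(0.80, 0.15, 0.05),
                         sources = c("interpolated", "anchored", "expert")) {
  stopifnot(abs(sum(weights) - 1) < 1e-9, length(weights) == length(sources))
  raw <- n * weights
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  sample(rep(sources, counts))
}

#' Simulated expert ordinal ratings
#'
#' Stand-in for expert annotation (no human raters ship with the package):
#' the ground-truth score is rescaled to a 0-10 analog scale, perturbed
#' with rater noise and discretized. Used to exercise the weighted-kappa
#' path and the expert label source.
#'
#' @param truth numeric ground-truth values.
#' @param lo,hi range of `truth` mapped onto the 0-10 scale.
#' @param noise_sd rater noise on the 0-10 scale, default 0.8.
#' @return integer ratings in `0..10`.
#' @export
make_expert_ratings <- function(truth, lo = min(truth), hi = max(truth),
                                noise_sd = 0.8) {
  z <- (truth - lo) / max(hi - lo, 1e-12) * 10
  r <- round(z + stats::rnorm(length(z), 0, noise_sd))
  pmin(pmax(r, 0), 10)
}

#' Grouped cross-validation harness
#'
#' Evaluates a model-fitting routine under grouped k-fold or
#' leave-one-subject-out cross-validation, asserting the absence of
#' subject leakage in every fold, and reports per-fold R^2, MAE and
#' Spearman rho.
#'
#' @param X feature matrix.
#' @param y numeric labels.
#' @param groups subject ids.
#' @param scheme `"groupkfold"` (k = 5) or `"losocv"`.
#' @param fit_fun function `(X_train, y_train, groups_train)` returning a
#'   model; default fits the package's stacked scoring model on the single
#'   task.
#' @param predict_fun function `(model, X_test)` returning predictions;
#'   default matches the default `fit_fun`.
#' @param k folds for `"groupkfold"`, default 5.
#' @return list with `per_fold` (data frame), `mean` and `sd` of each
#'   metric.
#' @export
cv_harness <- function(X, y, groups, scheme = c("groupkfold", "losocv"),
                       fit_fun = NULL, predict_fun = NULL, k = 5) {
  scheme <- match.arg(scheme)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (is.null(fit_fun)) {
    cfg1 <- scoring_config(tasks = "y", w_m = 1, alpha_m = 1, k_folds = 3)
    fit_fun <- function(Xtr, ytr, gtr)
      fit_scoring_model(Xtr, matrix(ytr, ncol = 1), gtr, cfg1)
    predict_fun <- function(model, Xte)
      as.numeric(predict_scores(model, Xte, scale = "raw"))
  }
  if (is.null(predict_fun)) stop("predict_fun required with a custom fit_fun")
  kk <- if (scheme == "losocv") length(unique(groups)) else k
  folds <- group_kfold(groups, kk)
  per_fold <- data.frame(fold = seq_along(folds), R2 = NA_real_,
                         MAE = NA_real_, spearman = NA_real_)
  for (f in seq_along(folds)) {
    val <- folds[[f]]
    assert_no_leakage(groups, val)
    model <- fit_fun(X[-val, , drop = FALSE], y[-val], groups[-val])
    pred <- predict_fun(model, X[val, , drop = FALSE])
    res <- y[val] - pred
    per_fold$R2[f] <- 1 - sum(res^2) / sum((y[val] - mean(y[val]))^2)
    per_fold$MAE[f] <- mean(abs(res))
    per_fold$spearman[f] <- suppressWarnings(
      stats::cor(y[val], pred, method = "spearman"))
  }
  list(per_fold = per_fold,
       mean = colMeans(per_fold[, -1]),
       sd = apply(per_fold[, -1], 2, stats::sd))
}

#' Paired t-test with Hedges-corrected effect size
#'
#' Paired t statistic and confidence interval for the mean change, plus
#' the small-sample-corrected standardized effect size
#' `d = (mean_post - mean_pre) / s_pooled * (1 - 3 / (4(n-1) - 1))` with
#' `s_pooled = sqrt((s_pre^2 + s_post^2) / 2)`.
#'
#' @param pre,post paired numeric samples of equal length (n >= 3).
#' @param conf confidence level, default 0.95.
#' @return list with `t`, `p`, `d_hedges`, `ci` (CI for the mean change),
#'   `mean_change`, `n`.
#' @export
paired_t_hedges <- function(pre, post, conf = 0.95) {
  stopifnot(length(pre) == length(post), length(pre) >= 3)
  if (stats::sd(post - pre) == 0 && all(post == pre)) {
    # degenerate: no change at all
    return(list(t = 0, p = 1, d_hedges = 0, ci = c(0, 0),
                mean_change = 0, n = length(pre)))
  }
  if (stats::sd(pre) == 0 && stats::sd(post) == 0)
    stop("zero variance in both samples")
  n <- length(pre)
  tt <- stats::t.test(post, pre, paired = TRUE, conf.level = conf)
  s_pooled <- sqrt((stats::var(pre) + stats::var(post)) / 2)
  corr <- 1 - 3 / (4 * (n - 1) - 1)
  d <- (mean(post) - mean(pre)) / s_pooled * corr
  list(t = unname(tt$statistic), p = tt$p.value, d_hedges = d,
       ci = as.numeric(tt$conf.int), mean_change = mean(post - pre), n = n)
}

#' ICC(2,1): two-way random effects, absolute agreement, single measure
#'
#' Computed from the standard ANOVA mean-squares decomposition of a
#' subjects x raters matrix.
#'
#' @param ratings numeric matrix, rows = subjects (>= 5), cols = raters
#'   (>= 2).
#' @return ICC(2,1) estimate.
#' @export
icc_2_1 <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings)
  k <- ncol(ratings)
  stopifnot(n >= 5, k >= 2)
  grand <- mean(ratings)
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  MSR <- k * sum((row_m - grand)^2) / (n - 1)
  MSC <- n * sum((col_m - grand)^2) / (k - 1)
  SSE <- sum((ratings - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  MSE <- SSE / ((n - 1) * (k - 1))
  (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
}

#' Quadratic weighted kappa
#'
#' Cohen's kappa with quadratic agreement weights
#' `w_ij = 1 - ((i - j) / (K - 1))^2` over a shared ordinal scale.
#'
#' @param r1,r2 ratings on the same ordinal scale (integers or factors).
#' @param levels optional full set of scale levels (defaults to the union
#'   observed).
#' @return weighted kappa in `[-1, 1]`.
#' @export
weighted_kappa <- function(r1, r2, levels = NULL) {
  stopifnot(length(r1) == length(r2))
  if (is.null(levels)) levels <- sort(unique(c(r1, r2)))
  K <- length(levels)
  if (K < 2) return(NA_real_)
  O <- table(factor(r1, levels = levels), factor(r2, levels = levels))
  O <- O / sum(O)
  E <- outer(rowSums(O), colSums(O))
  idx <- seq_len(K)
  W <- 1 - (outer(idx, idx, `-`) / (K - 1))^2
  po <- sum(W * O)
  pe <- sum(W * E)
  (po - pe) / (1 - pe)
}

#' Bonferroni-adjusted significance level
#'
#' @param alpha family-wise level, default 0.05.
#' @param m number of comparisons, default 5.
#' @return `alpha / m`.
#' @export
bonferroni_alpha <- function(alpha = 0.05, m = 5) {
  stopifnot(alpha > 0, m >= 1)
  alpha / m
}

#' Outcome-table arithmetic
#'
#' Derives absolute and relative changes from a table of baseline and
#' week-4 means: `change = week4 - baseline` and
#' `relative = 100 * change / baseline`.
#'
#' @param table data frame with columns `metric`, `baseline_mean`,
#'   `week4_mean` (as produced by [load_outcome_table()]).
#' @return the table with `change` and `relative_change_pct` columns
#'   appended.
#' @export
outcome_arithmetic <- function(table) {
  stopifnot(all(c("metric", "baseline_mean", "week4_mean") %in% names(table)))
  table$change <- table$week4_mean - table$baseline_mean
  table$relative_change_pct <- 100 * table$change / table$baseline_mean
  table
}

#' Session completion percentage
#'
#' @param done sessions completed.
#' @param scheduled sessions scheduled.
#' @return completion rate in percent (1 d.p. matches reporting practice
#'   only when rounded by the caller).
#' @export
completion_rate <- function(done, scheduled) {
  stopifnot(scheduled > 0, done >= 0, done <= scheduled)
  100 * done / scheduled
}

#' Load the bundled clinical outcome table
#'
#' Baseline and week-4 means/SDs of the adaptive-control and clinical
#' outcome metrics shipped as a plain-text CSV; input to
#' [outcome_arithmetic()].
#'
#' @return data frame with columns `metric, baseline_mean, baseline_sd,
#'   week4_mean, week4_sd`.
#' @export
load_outcome_table <- function() {
  path <- system.file("extdata", "clinical_outcomes.csv",
                      package = "rehabloop", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
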