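#' Scoring model configuration
#'
#' Hyperparameters of the stacked scoring model and the online inference
#' chain. Defaults: random forest with 200 trees, depth limit 8 and minimum
#' leaf size 5; RBF support vector regression with gamma 0.01, cost 10,
#' epsilon 0.1; ridge meta-learner penalty 0.5; Huber delta 1 on
#' standardized residuals; task set FMA-proxy / ARAT-proxy / ROMn / SPARC
#' with clinical-prior weights 0.4/0.3/0.2/0.1; equal composite
#' coefficients; smoothing rate 0.3; online bias learning rate 0.1.
#'
#' @param tasks character vector of task label names.
#' @param w_m task weights for the Huber objective (same order as `tasks`).
#' @param alpha_m composite coefficients, `alpha_m >= 0`, summing to 1.
#' @param sigmoid_a,sigmoid_b composite calibration parameters.
#' @param huber_delta Huber threshold on standardized residuals.
#' @param rf_trees,rf_depth,rf_min_leaf random-forest spec.
#' @param svr_gamma,svr_cost,svr_epsilon RBF-SVR spec.
#' @param ridge_lambda meta-learner L2 penalty.
#' @param lambda_smooth exponential smoothing rate in `(0, 1]`.
#' @param eta_bias online bias learning rate in `(0, 1)`.
#' @param quality_tau window quality threshold; windows with `Q <
#'   quality_tau` get fitting weight `Q / quality_tau`.
#' @param calibration `"isotonic"` or `"platt"`.
#' @param k_folds grouped cross-validation folds for stacking.
#' @param seed RNG seed recorded in the bundle.
#' @return object of class `scoring_config`.
#' @export
scoring_config <- function(tasks = c("fma_proxy", "arat_proxy", "romn", "sparc"),
                           w_m = c(0.4, 0.3, 0.2, 0.1),
                           alpha_m = NULL,
                           sigmoid_a = 1, sigmoid_b = 0,
                           huber_delta = 1.0,
                           rf_trees = 200, rf_depth = 8, rf_min_leaf = 5,
                           svr_gamma = 0.01, svr_cost = 10, svr_epsilon = 0.1,
                           ridge_lambda = 0.5,
                           lambda_smooth = 0.3, eta_bias = 0.1,
                           quality_tau = 0.9,
                           calibration = c("isotonic", "platt"),
                           k_folds = 5, seed = 42L) {
  calibration <- match.arg(calibration)
  if (is.null(alpha_m)) alpha_m <- rep(1 / length(tasks), length(tasks))
  stopifnot(length(w_m) == length(tasks), length(alpha_m) == length(tasks),
            all(alpha_m >= 0), abs(sum(alpha_m) - 1) < 1e-9,
            huber_delta > 0, lambda_smooth > 0, lambda_smooth <= 1,
            eta_bias > 0, eta_bias < 1)
  structure(as.list(environment()), class = "scoring_config")
}

#' Weighted Huber loss
#'
#' `sum_i sum_m w_m H_delta(r_im)` with `H_delta(r) = r^2/2` for
#' `|r| <= delta`, else `delta (|r| - delta/2)`.
#'
#' @param residuals numeric matrix (rows = observations, cols = tasks) or
#'   vector (single task).
#' @param w_m task weights (recycled over columns).
#' @param delta Huber threshold (> 0).
#' @return scalar loss.
#' @export
weighted_huber <- function(residuals, w_m = 1, delta = 1) {
  if (delta <= 0) stop("delta must be > 0")
  r <- as.matrix(residuals)
  w <- rep(w_m, length.out = ncol(r))
  H <- ifelse(abs(r) <= delta, r^2 / 2, delta * (abs(r) - delta / 2))
  sum(sweep(H, 2, w, `*`))
}

#' Grouped k-fold split
#'
#' Assigns whole groups to folds (balanced by group count) so no subject
#' appears in both the training and validation side of any fold.
#'
#' @param groups vector of group ids (one per row).
#' @param k number of folds.
#' @return list of integer vectors of validation row indices.
#' @export
group_kfold <- function(groups, k = 5) {
  ug <- unique(groups)
  if (length(ug) < k) stop("need at least k groups")
  fold_of <- rep(seq_len(k), length.out = length(ug))
  lapply(seq_len(k), function(f) which(groups %in% ug[fold_of == f]))
}

# stop if any group straddles the train/validation boundary
assert_no_leakage <- function(groups, val_idx) {
  tr <- unique(groups[-val_idx])
  va <- unique(groups[val_idx])
  if (length(intersect(tr, va)) > 0)
    stop("subject leakage: group(s) present in both train and validation")
  invisible(TRUE)
}

# weighted ridge with IRLS Huber reweighting; Z without intercept column
huber_ridge <- function(Z, y, lambda, delta, w0 = NULL, iters = 10) {
  Z1 <- cbind(1, Z)
  if (is.null(w0)) w0 <- rep(1, length(y))
  pen <- diag(c(0, rep(lambda, ncol(Z))))
  w <- w0
  beta <- rep(0, ncol(Z1))
  for (it in seq_len(iters)) {
    A <- t(Z1 * w) %*% Z1 + pen
    beta_new <- solve(A, t(Z1 * w) %*% y)
    beta <- as.numeric(beta_new)
    r <- y - as.numeric(Z1 %*% beta)
    hub <- ifelse(abs(r) <= delta, 1, delta / pmax(abs(r), 1e-12))
    w <- w0 * hub
  }
  beta
}

fit_base_learners <- function(X, y, cfg) {
  rf <- randomForest::randomForest(
    x = X, y = y, ntree = cfg$rf_trees,
    maxnodes = min(2^cfg$rf_depth, max(2L, nrow(X))),
    nodesize = cfg$rf_min_leaf, keep.inbag = TRUE)
  sv <- e1071::svm(x = X, y = y, type = "eps-regression", kernel = "radial",
                   gamma = cfg$svr_gamma, cost = cfg$svr_cost,
                   epsilon = cfg$svr_epsilon,
                   scale = apply(X, 2, stats::sd) > 0)
  list(rf = rf, svr = sv)
}

#' Fit the stacked scoring model
#'
#' Per task, a random forest and an RBF support vector regressor are fitted
#' and their out-of-fold predictions (grouped k-fold by subject, leakage
#' guarded) feed a linear ridge meta-learner together with optional context
#' columns. The meta-learner is fitted by iteratively reweighted least
#' squares under the weighted Huber objective; window quality weights
#' `Q/tau` downweight low-quality windows. Base learners are refitted on
#' all data for deployment.
#'
#' @param X numeric feature matrix (named columns).
#' @param Y numeric label matrix, one column per task in
#'   `config$tasks` order (a vector is treated as a single task).
#' @param groups subject ids, one per row (no leakage across folds).
#' @param config a [scoring_config()].
#' @param context optional numeric context matrix (e.g. current difficulty,
#'   ROM baseline) appended to the meta-learner input.
#' @param quality optional per-row quality Q in [0, 1].
#' @return object of class `model_bundle`.
#' @export
fit_scoring_model <- function(X, Y, groups, config = scoring_config(),
                              context = NULL, quality = NULL) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  M <- ncol(Y)
  n <- nrow(X)
  stopifnot(length(groups) == n, nrow(Y) == n)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (!is.null(context)) context <- as.matrix(context)
  if (is.null(quality)) quality <- rep(1, n)
  w_q <- pmin(1, quality / config$quality_tau)

  set.seed(config$seed)
  folds <- group_kfold(groups, config$k_folds)
  # per-task label standardizers
  y_mu <- colMeans(Y)
  y_sd <- apply(Y, 2, stats::sd)
  if (any(y_sd == 0)) stop("constant task labels cannot be standardized")
  Yz <- sweep(sweep(Y, 2, y_mu), 2, y_sd, `/`)

  oof_rf <- matrix(NA_real_, n, M)
  oof_sv <- matrix(NA_real_, n, M)
  for (f in seq_along(folds)) {
    val <- folds[[f]]
    assert_no_leakage(groups, val)
    for (m in seq_len(M)) {
      bl <- fit_base_learners(X[-val, , drop = FALSE], Yz[-val, m], config)
      oof_rf[val, m] <- predict(bl$rf, X[val, , drop = FALSE])
      oof_sv[val, m] <- predict(bl$svr, X[val, , drop = FALSE])
    }
  }

  base <- vector("list", M)
  meta <- vector("list", M)
  for (m in seq_len(M)) {
    base[[m]] <- fit_base_learners(X, Yz[, m], config)
    Z <- cbind(rf = oof_rf[, m], svr = oof_sv[, m])
    if (!is.null(context)) Z <- cbind(Z, context)
    meta[[m]] <- huber_ridge(Z, Yz[, m], config$ridge_lambda,
                             config$huber_delta, w0 = w_q)
  }
  structure(list(base = base, meta = meta, config = config,
                 y_mu = y_mu, y_sd = y_sd,
                 feature_names = colnames(X),
                 feature_hash = paste(colnames(X), collapse = "|"),
                 n_context = if (is.null(context)) 0L else ncol(context),
                 bias = 0,
                 oof = list(rf = oof_rf, svr = oof_sv)),
            class = "model_bundle")
}

#' Predict per-task scores from a fitted bundle
#'
#' Runs both base learners and the ridge fusion for each task; the online
#' fusion bias `bundle$bias` (updated by [bias_correct()]) is added to the
#' standardized fused prediction.
#'
#' @param bundle a fitted `model_bundle`.
#' @param X feature matrix with the training columns (order and names are
#'   checked against the stored feature hash).
#' @param context context matrix matching the one used at fit time.
#' @param scale `"standardized"` (default) or `"raw"` label units.
#' @return numeric matrix, one column per task.
#' @export
predict_scores <- function(bundle, X, context = NULL,
                           scale = c("standardized", "raw")) {
  scale <- match.arg(scale)
  stopifnot(inherits(bundle, "model_bundle"))
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- bundle$feature_names
  if (paste(colnames(X), collapse = "|") != bundle$feature_hash)
    stop("feature hash mismatch: model was trained on different features")
  nctx <- if (is.null(context)) 0L else ncol(as.matrix(context))
  if (nctx != bundle$n_context)
    stop("context dimension mismatch with training")
  M <- length(bundle$base)
  out <- matrix(NA_real_, nrow(X), M)
  for (m in seq_len(M)) {
    rf_p <- predict(bundle$base[[m]]$rf, X)
    sv_p <- predict(bundle$base[[m]]$svr, X)
    Z <- cbind(1, rf_p, sv_p)
    if (!is.null(context)) Z <- cbind(Z, as.matrix(context))
    out[, m] <- as.numeric(Z %*% bundle$meta[[m]]) + bundle$bias
  }
  if (scale == "raw")
    out <- sweep(sweep(out, 2, bundle$y_sd, `*`), 2, bundle$y_mu, `+`)
  colnames(out) <- bundle$config$tasks[seq_len(M)]
  out
}

#' Composite score from standardized task components
#'
#' `S = sigmoid(a * sum(alpha_m z_m) + b)` with `alpha_m >= 0` summing
#' to 1, so S lies in (0, 1) and is monotone in every component.
#'
#' @param z numeric vector (one window) or matrix (rows = windows) of
#'   standardized task components.
#' @param config a [scoring_config()] providing `alpha_m`, `sigmoid_a`,
#'   `sigmoid_b`.
#' @return composite score(s) in `(0, 1)`.
#' @export
composite_score <- function(z, config = scoring_config()) {
  z <- rbind(z)
  a <- config$alpha_m[seq_len(ncol(z))]
  stopifnot(all(a >= 0), abs(sum(a) - 1) < 1e-9)
  as.numeric(stats::plogis(config$sigmoid_a * (z %*% a) + config$sigmoid_b))
}

#' Baseline-to-healthy reference score
#'
#' `clip((yhat - mu_0) / (mu_ref - mu_0), 0, 1)`: 0 at the individual
#' baseline, 1 at the healthy reference.
#'
#' @param yhat predicted value(s).
#' @param mu_0 individual baseline expectation.
#' @param mu_ref healthy reference expectation (must differ from `mu_0`).
#' @return reference score(s) in `[0, 1]`.
#' @export
reference_score <- function(yhat, mu_0, mu_ref) {
  if (mu_ref == mu_0) stop("mu_ref must differ from mu_0")
  pmin(pmax((yhat - mu_0) / (mu_ref - mu_0), 0), 1)
}

#' Align composite and reference scores
#'
#' Isotonic mode fits a monotone non-decreasing step map (pool adjacent
#' violators via [stats::isoreg()]); Platt mode fits a two-parameter
#' sigmoid by least squares. Constant inputs return the identity map with
#' a warning.
#'
#' @param s composite scores (predictor).
#' @param s_ref reference scores (target), same length (>= 20 pairs).
#' @param mode `"isotonic"` or `"platt"`.
#' @return a calibration function mapping new scores to `[0, 1]`.
#' @export
calibrate_scores <- function(s, s_ref, mode = c("isotonic", "platt")) {
  mode <- match.arg(mode)
  stopifnot(length(s) == length(s_ref), length(s) >= 20)
  if (stats::sd(s) == 0 || stats::sd(s_ref) == 0) {
    warning("constant calibration input; returning identity map")
    return(identity)
  }
  if (mode == "isotonic") {
    o <- order(s)
    ir <- stats::isoreg(s[o], s_ref[o])
    xs <- ir$x
    ys <- ir$yf
    function(x) {
      y <- stats::approx(xs, ys, xout = x, method = "constant", rule = 2,
                         ties = "ordered")$y
      pmin(pmax(y, 0), 1)
    }
  } else {
    fit <- stats::optim(c(a = 1, b = 0), function(p)
      sum((stats::plogis(p[1] * s + p[2]) - s_ref)^2), method = "BFGS")
    a <- fit$par[1]; b <- fit$par[2]
    function(x) stats::plogis(a * x + b)
  }
}

#' Exponential smoothing of the instantaneous score
#'
#' `S~_t = lambda S_t + (1 - lambda) S~_{t-1}`, initialized at the first
#' score.
#'
#' @param S numeric vector of instantaneous scores.
#' @param lambda smoothing rate in `(0, 1]`.
#' @param init optional previous smoothed value carried over from an
#'   earlier call.
#' @return numeric vector of smoothed scores.
#' @export
smooth_score <- function(S, lambda = 0.3, init = NULL) {
  stopifnot(lambda > 0, lambda <= 1)
  out <- numeric(length(S))
  prev <- if (is.null(init)) S[1] else init
  if (is.null(init)) { out[1] <- S[1]; start <- 2 } else start <- 1
  if (is.null(init) && length(S) == 1) return(out)
  for (t in start:length(S)) {
    prev <- lambda * S[t] + (1 - lambda) * prev
    out[t] <- prev
  }
  out
}

#' Online fusion-bias correction
#'
#' `b_{t+1} = b_t + eta (S_bar - S_hat_bar)`: only the fusion-layer bias is
#' adapted between sessions, nudging the predicted session mean toward the
#' session target.
#'
#' @param b current bias.
#' @param S_bar session target mean score.
#' @param S_hat_bar session predicted mean score.
#' @param eta learning rate in `(0, 1)`.
#' @return updated bias.
#' @export
bias_correct <- function(b, S_bar, S_hat_bar, eta = 0.1) {
  stopifnot(eta > 0, eta < 1)
  b + eta * (S_bar - S_hat_bar)
}

#' Predictive uncertainty of the score
#'
#' `sigma_t = sqrt(w_tree * Var_trees + w_resid * EMA(residual^2))`: the
#' between-tree variance of the random forest for the first task plus an
#' exponential moving average of recent squared SVR residuals. Without
#' residual history only the tree variance contributes.
#'
#' @param bundle a fitted `model_bundle`.
#' @param X feature matrix of the windows to score.
#' @param residuals optional numeric vector of recent residuals
#'   (standardized units).
#' @param w_tree,w_resid component weights, default 0.5 each.
#' @param ema_alpha EMA rate for the residual term, default 0.1.
#' @return numeric vector of uncertainties (>= 0).
#' @export
score_uncertainty <- function(bundle, X, residuals = NULL,
                              w_tree = 0.5, w_resid = 0.5, ema_alpha = 0.1) {
  stopifnot(inherits(bundle, "model_bundle"))
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- bundle$feature_names
  pr <- predict(bundle$base[[1]]$rf, X, predict.all = TRUE)
  tree_var <- apply(rbind(pr$individual), 1, stats::var)
  resid_term <- 0
  if (!is.null(residuals) && length(residuals) > 0) {
    ema <- residuals[1]^2
    for (r in residuals[-1]) ema <- ema_alpha * r^2 + (1 - ema_alpha) * ema
    resid_term <- ema
  } else {
    w_tree <- w_tree + w_resid
    w_resid <- 0
  }
  sqrt(pmax(w_tree * tree_var + w_resid * resid_term, 0))
}

#' Linear intent classifier (active vs rest)
#'
#' A linear support vector machine on sEMG features with decision function
#' `f(x) = w'x + b`; `f > 0` is classified as active, and the boundary
#' `f = 0` is conservatively assigned to rest.
#'
#' @param X feature matrix.
#' @param y factor or character labels with levels `"rest"`, `"active"`.
#' @param cost SVM cost parameter.
#' @return object of class `intent_model` with fields `w`, `b`.
#' @export
intent_fit <- function(X, y, cost = 1) {
  y <- factor(y, levels = c("rest", "active"))
  if (nlevels(droplevels(y)) < 2) stop("need both classes to train")
  X <- as.matrix(X)
  fit <- e1071::svm(x = X, y = y, type = "C-classification",
                    kernel = "linear", cost = cost, scale = FALSE)
  w <- as.numeric(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # e1071 orders the decision value by the first factor level ("rest");
  # flip so positive margin means "active"
  w <- -w; b <- -b
  structure(list(w = w, b = b), class = "intent_model")
}

#' @rdname intent_fit
#' @param model a fitted `intent_model` (or a list with `w`, `b`).
#' @param x feature vector or matrix to classify.
#' @return list with `class` (`"active"`/`"rest"`) and `margin` (f(x)).
#' @export
intent_classify <- function(model, x) {
  if (is.null(model$w)) stop("untrained intent model")
  x <- rbind(x)
  f <- as.numeric(x %*% model$w + model$b)
  list(class = ifelse(f > 0, "active", "rest"), margin = f)
}
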