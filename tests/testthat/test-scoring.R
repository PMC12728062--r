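test_that("weighted Huber loss matches hand values and is C1 at the knee", {
  expect_equal(weighted_huber(0.5, w_m = 1, delta = 1), 0.125)
  expect_equal(weighted_huber(2, w_m = 1, delta = 1), 1.5)
  # both branches agree at |r| = delta
  d <- 0.7
  quad <- d^2 / 2
  lin <- d * (d - d / 2)
  expect_equal(quad, lin)
  expect_equal(weighted_huber(d, delta = d), quad)
  # task weighting
  R <- cbind(c(0.5, 0.5), c(2, 2))
  expect_equal(weighted_huber(R, w_m = c(1, 2), delta = 1),
               2 * 0.125 + 2 * 2 * 1.5)
  expect_error(weighted_huber(1, delta = 0), "delta")
})

test_that("composite score: sigmoid identities and monotonicity", {
  cfg <- scoring_config(tasks = "t", w_m = 1, alpha_m = 1)
  expect_equal(composite_score(0, cfg), 0.5)
  expect_equal(composite_score(1, cfg), 1 / (1 + exp(-1)), tolerance = 1e-9)
  cfg4 <- scoring_config()
  grid <- seq(-3, 3, by = 0.5)
  for (m in 1:4) {
    z <- matrix(0, length(grid), 4)
    z[, m] <- grid
    s <- composite_score(z, cfg4)
    expect_true(all(diff(s) > 0))
    expect_true(all(s > 0 & s < 1))
  }
})

test_that("reference score maps baseline to 0, healthy reference to 1", {
  expect_equal(reference_score(30, 30, 60), 0)
  expect_equal(reference_score(60, 30, 60), 1)
  expect_equal(reference_score(45, 30, 60), 0.5)
  expect_equal(reference_score(90, 30, 60), 1)   # clipped
  expect_error(reference_score(45, 30, 30), "differ")
})

test_that("calibration: identity on aligned pairs, PAV collapse, Platt recovery", {
  set.seed(131)
  s <- seq(0.05, 0.95, length.out = 50)
  cal <- calibrate_scores(s, s, mode = "isotonic")
  expect_lt(max(abs(cal(s) - s)), 0.02)
  # reversed ordering collapses to a constant map (brute-force PAV mean)
  rev_cal <- calibrate_scores(s, rev(s), mode = "isotonic")
  expect_lt(max(abs(rev_cal(s) - mean(s))), 1e-9)
  # Platt on logistic-generated data recovers the slope
  a_true <- 3; b_true <- -1.5
  x <- stats::runif(1000, -2, 2)
  y <- stats::plogis(a_true * x + b_true)
  pl <- calibrate_scores(x, y, mode = "platt")
  xs <- seq(-2, 2, by = 0.01)
  expect_lt(max(abs(pl(xs) - stats::plogis(a_true * xs + b_true))), 0.01)
  expect_warning(calibrate_scores(rep(0.5, 30), stats::runif(30)), "constant")
})

test_that("score smoothing recursion, bounds and bias correction", {
  expect_equal(smooth_score(c(0.2, 0.8, 0.4), lambda = 1), c(0.2, 0.8, 0.4))
  expect_equal(smooth_score(c(0.5, 0.9), lambda = 0.3)[2], 0.62)
  set.seed(141)
  S <- stats::runif(200)
  sm <- smooth_score(S, 0.3)
  expect_true(all(sm >= cummin(S) - 1e-12 & sm <= cummax(S) + 1e-12))
  # bias correction
  expect_equal(bias_correct(0.1, 0.7, 0.7, eta = 0.5), 0.1)
  expect_equal(bias_correct(0, 0.7, 0.6, eta = 0.5), 0.05)
  # repeated application converges geometrically at rate (1 - eta)
  b <- 0; target <- 0.8; eta <- 0.25
  errs <- numeric(20)
  for (i in 1:20) {
    pred <- 0.5 + b          # predicted mean tracks bias linearly
    errs[i] <- target - pred
    b <- bias_correct(b, target, pred, eta)
  }
  expect_equal(errs[-1] / errs[-20], rep(1 - eta, 19), tolerance = 1e-9)
})

test_that("group k-fold guards against subject leakage", {
  groups <- rep(1:6, each = 10)
  folds <- group_kfold(groups, 3)
  for (f in folds) expect_silent(assert_no_leakage(groups, f))
  # constructed leaky split must trigger the guard
  leaky <- c(which(groups == 1), which(groups == 2)[1:5])
  expect_error(assert_no_leakage(groups, leaky), "leakage")
  expect_error(group_kfold(rep(1, 10), 3), "at least")
})

test_that("stacked model learns a noise-free linear target and fails on permuted labels", {
  set.seed(151)
  n <- 240
  groups <- rep(1:8, each = 30)
  X <- matrix(stats::rnorm(n * 5), n, 5,
              dimnames = list(NULL, paste0("f", 1:5)))
  y <- 2 * X[, 1]
  cfg <- scoring_config(tasks = "t", w_m = 1, alpha_m = 1, k_folds = 4)
  bundle <- fit_scoring_model(X, y, groups, cfg)
  # held-out subjects
  set.seed(152)
  X_new <- matrix(stats::rnorm(300), 60, 5,
                  dimnames = list(NULL, paste0("f", 1:5)))
  y_new <- 2 * X_new[, 1]
  pred <- as.numeric(predict_scores(bundle, X_new, scale = "raw"))
  r2 <- 1 - sum((y_new - pred)^2) / sum((y_new - mean(y_new))^2)
  expect_gte(r2, 0.9)
  # permutation null over several seeds
  r2p <- vapply(1:5, function(s) {
    set.seed(160 + s)
    cv <- cv_harness(X, sample(y), groups, scheme = "groupkfold", k = 4)
    cv$mean[["R2"]]
  }, numeric(1))
  expect_true(all(r2p <= 0.1))
})

test_that("inference is deterministic and guards train/serve skew", {
  set.seed(161)
  X <- matrix(stats::rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- X[, 1] + stats::rnorm(100, 0, 0.1)
  groups <- rep(1:5, each = 20)
  cfg <- scoring_config(tasks = "t", w_m = 1, alpha_m = 1, k_folds = 5)
  b1 <- fit_scoring_model(X, y, groups, cfg)
  b2 <- fit_scoring_model(X, y, groups, cfg)
  xq <- X[1:7, ]
  expect_identical(predict_scores(b1, xq), predict_scores(b2, xq))
  expect_identical(predict_scores(b1, xq), predict_scores(b1, xq))
  bad <- xq; colnames(bad) <- c("a", "b", "zz")
  expect_error(predict_scores(b1, bad), "hash")
})

test_that("uncertainty: zero for perfectly replicated targets, larger off the training hull", {
  set.seed(171)
  cfg <- scoring_config(tasks = "t", w_m = 1, alpha_m = 1, k_folds = 3,
                        rf_trees = 100)
  # steep-at-the-boundary target: extrapolation beyond the training hull
  # depends on which edge points each bootstrap saw, so trees disagree
  outside_gt_inside <- logical(20)
  for (s in 1:20) {
    set.seed(200 + s)
    x <- matrix(stats::runif(150, -1, 1), ncol = 1, dimnames = list(NULL, "x"))
    y <- exp(3 * x[, 1])
    bundle <- fit_scoring_model(x, y, groups = rep(1:3, each = 50), cfg)
    s_in <- mean(score_uncertainty(bundle, matrix(c(-0.3, 0, 0.3), ncol = 1,
                                                  dimnames = list(NULL, "x"))))
    s_out <- mean(score_uncertainty(bundle, matrix(c(1.3, 1.5), ncol = 1,
                                                   dimnames = list(NULL, "x"))))
    outside_gt_inside[s] <- s_out > s_in
  }
  expect_gte(mean(outside_gt_inside), 0.9)
  # duplicated target: all trees agree, residuals zero
  xd <- matrix(rep(c(0, 1), each = 30), ncol = 1, dimnames = list(NULL, "x"))
  yd <- rep(c(0, 1), each = 30)
  bd <- suppressWarnings(   # two-level regression target is intentional
    fit_scoring_model(xd, yd, groups = rep(1:3, 20), cfg))
  sig <- score_uncertainty(bd, xd[c(1, 31), , drop = FALSE],
                           residuals = c(0, 0, 0))
  expect_lt(max(sig), 0.05)
})

test_that("intent classification: margins, tie-break and separable accuracy", {
  m <- structure(list(w = c(1, -1), b = 0), class = "intent_model")
  res <- intent_classify(m, c(2, 1))
  expect_equal(res$class, "active")
  expect_equal(res$margin, 1)
  # boundary goes conservatively to rest
  expect_equal(intent_classify(m, c(1, 1))$class, "rest")
  expect_error(intent_classify(list(w = NULL), c(1, 1)), "untrained")
  # two Gaussian blobs, margin 4 sd: accuracy >= 0.99
  set.seed(181)
  n <- 200
  Xtr <- rbind(matrix(stats::rnorm(n, 0, 1), ncol = 2),
               matrix(stats::rnorm(n, 8, 1), ncol = 2))
  ytr <- rep(c("rest", "active"), each = n / 2)
  fit <- intent_fit(Xtr, ytr)
  Xte <- rbind(matrix(stats::rnorm(n, 0, 1), ncol = 2),
               matrix(stats::rnorm(n, 8, 1), ncol = 2))
  yte <- rep(c("rest", "active"), each = n / 2)
  acc <- mean(intent_classify(fit, Xte)$class == yte)
  expect_gte(acc, 0.99)
  expect_error(intent_fit(Xtr, rep("rest", nrow(Xtr))), "both classes")
})
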