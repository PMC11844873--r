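test_that("regression metrics: perfect, mean, and hand-computed cases", {
  y <- c(1, 2, 3, 4)
  expect_equal(regression_metrics(y, y), list(r2 = 1, rmse = 0))
  expect_equal(regression_metrics(y, rep(mean(y), 4))$r2, 0)
  m <- regression_metrics(y, c(2, 2, 2, 2))
  expect_equal(m$r2, -0.2)
  expect_equal(m$rmse, sqrt(1.5))
  expect_error(regression_metrics(c(2, 2, 2), c(1, 2, 3)), "constant")
})

test_that("classification metrics reproduce the hand-worked confusion table", {
  # 9 TP, 3 FP, 10 TN, 2 FN at threshold 0.5 with 0/1 'continuous' scores
  y_true <- c(rep(1, 11), rep(0, 13))
  y_pred <- c(rep(1, 9), rep(0, 2), rep(1, 3), rep(0, 10))
  m <- classification_metrics(y_true, y_pred, 0.5)
  expect_equal(m$ppv, 0.75)
  expect_equal(m$npv, 0.8333, tolerance = 1e-4)
  expect_equal(m$sensitivity, 0.8182, tolerance = 1e-4)
  expect_equal(m$specificity, 0.7692, tolerance = 1e-4)
  expect_equal(unname(m$confusion), c(9, 3, 10, 2))
})

test_that("AUC: perfect separation, constant scores, and a pROC cross-check", {
  y <- c(10, 20, 30, 50, 60, 70)
  sep <- classification_metrics(y, c(1, 2, 3, 11, 12, 13), 40)
  expect_equal(sep$auc, 1)
  expect_equal(sep$sensitivity, 0)   # binary thresholding of low-scale scores
  const <- classification_metrics(y, rep(5, 6), 40)
  expect_equal(const$auc, 0.5)
  expect_error(classification_metrics(c(50, 60), c(1, 2), 40), "both")

  skip_if_not_installed("pROC")
  set.seed(71)
  yt <- rnorm(60, 35, 12); yp <- 0.6 * yt + rnorm(60, 0, 8)
  ours <- classification_metrics(yt, yp, 35)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(yt >= 35, yp, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("nested CV recovers a noiseless linear signal and fails on permuted targets", {
  fx <- .toy_regression(n = 35, r2 = 0.99999, seed = 11)
  fit <- nested_cv(fx$X, fx$eta, model_spec("elasticnet"), outer = "loo",
                   inner_k = 5, seed = 2)
  expect_gte(fit$metrics$r2, 0.99)
  set.seed(12)
  fitp <- nested_cv(fx$X, sample(fx$y), model_spec("elasticnet"),
                    outer = "loo", inner_k = 5, seed = 2)
  expect_lte(fitp$metrics$r2, 0.05)
})

test_that("a singleton grid equals a plain LOO fit-predict oracle", {
  fx <- .toy_regression(n = 25, seed = 13)
  spec1 <- model_spec("elasticnet",
                      grid = list(list(alpha = 0.5, lambda = 0.3)))
  fit <- nested_cv(fx$X, fx$y, spec1, outer = "loo", inner_k = 4, seed = 5)
  oracle <- vapply(seq_along(fx$y), function(i) {
    Xtr <- unclass(fx$X)[-i, , drop = FALSE]
    mu <- colMeans(Xtr); sdv <- apply(Xtr, 2, sd)
    Zs <- sweep(sweep(Xtr, 2, mu), 2, sdv, "/")
    ft <- glmnet::glmnet(Zs, fx$y[-i], alpha = 0.5, standardize = FALSE)
    zte <- (unclass(fx$X)[i, ] - mu) / sdv
    as.numeric(predict(ft, newx = matrix(zte, 1), s = 0.3))
  }, numeric(1))
  expect_equal(fit$predictions, oracle, tolerance = 1e-10)
})

test_that("held-out predictions are invariant to the held-out target (no leakage)", {
  fx <- .toy_regression(n = 24, seed = 17)
  for (fam in c("elasticnet", "random_forest")) {
    fit <- nested_cv(fx$X, fx$y, model_spec(fam), outer = "loo", inner_k = 4,
                     seed = 3)
    y_mut <- fx$y; y_mut[7] <- y_mut[7] + 500
    fit_mut <- nested_cv(fx$X, y_mut, model_spec(fam), outer = "loo",
                         inner_k = 4, seed = 3)
    expect_identical(fit$predictions[7], fit_mut$predictions[7])
  }
})

test_that("joint search with one model and one parcellation equals per-combo", {
  fx <- .toy_regression(n = 22, seed = 19)
  sp <- model_spec("elasticnet")
  a <- nested_cv(fx$X, fx$y, sp, outer = "loo", inner_k = 4, seed = 6)
  b <- nested_cv_joint(list(features = fx$X), fx$y, list(sp), outer = "loo",
                       inner_k = 4, seed = 6)
  expect_identical(a$predictions, b$predictions)
  expect_identical(a$metrics, b$metrics)
})

test_that("the informative parcellation wins most outer folds in the joint search", {
  set.seed(23)
  n <- 36
  fx <- .toy_regression(n = n, r2 = 0.9, seed = 23)
  noiseX <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("n", 1:6)))
  X_list <- list(signal = fx$X,
                 noise = feature_matrix(noiseX, rep("imaging", 6), rep(TRUE, 6)))
  fit <- nested_cv_joint(X_list, fx$y, list(model_spec("elasticnet")),
                         outer = "loo", inner_k = 5, seed = 8)
  expect_gte(mean(fit$chosen$set == "signal"), 0.8)
})

test_that("permutation null is centred at or below zero and deterministic", {
  fx <- .toy_regression(n = 30, seed = 29)
  pn <- permutation_null(fx$X, fx$y, n_permutations = 25, seed = 4)
  se <- sd(pn$r2) / sqrt(length(pn$r2))
  expect_lte(pn$mean, 0 + 3 * se)
  pn2 <- permutation_null(fx$X, fx$y, n_permutations = 25, seed = 4)
  expect_identical(pn$r2, pn2$r2)
})

test_that("importance: informative feature ranks first with the right sign", {
  fx <- .toy_regression(n = 40, r2 = 0.95, seed = 31)
  fit <- nested_cv(fx$X, fx$y, model_spec("elasticnet"), outer = 10,
                   inner_k = 5, seed = 9)
  imp <- feature_importance(fit)
  expect_equal(imp$feature[1], "x1")
  expect_gt(imp$median_importance[1], 0)
  expect_equal(coef(fit), setNames(imp$median_importance, imp$feature))
  # duplicated informative feature: the elastic net keeps both in play
  Xd <- cbind(unclass(fx$X), x1_dup = unclass(fx$X)[, "x1"])
  Xd <- feature_matrix(Xd, rep("imaging", ncol(Xd)), rep(TRUE, ncol(Xd)))
  fit_d <- nested_cv(Xd, fx$y, model_spec("elasticnet"), outer = 10,
                     inner_k = 5, seed = 9)
  cd <- coef(fit_d)
  expect_gt(cd[["x1"]], 0)
  expect_gt(cd[["x1_dup"]], 0)
})

test_that("tree importance carries the sign of the univariate correlation", {
  set.seed(37)
  n <- 60
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("up", "down", "null")))
  y <- 3 * X[, "up"] - 3 * X[, "down"] + rnorm(n, 0, 0.5)
  fit <- nested_cv(feature_matrix(X, rep("imaging", 3), rep(TRUE, 3)), y,
                   model_spec("random_forest"), outer = 6, inner_k = 4,
                   seed = 10)
  cf <- coef(fit)
  expect_gt(cf[["up"]], 0)
  expect_lt(cf[["down"]], 0)
})

test_that("severity_cv methods: predict, residuals, simulate, print", {
  fx <- .toy_regression(n = 25, seed = 41)
  fit <- nested_cv(fx$X, fx$y, model_spec("elasticnet"), outer = 5,
                   inner_k = 4, seed = 11)
  expect_equal(residuals(fit), fx$y - fitted(fit))
  pr <- predict(fit, unclass(fx$X))
  expect_length(pr, 25)
  expect_gt(cor(pr, fx$y), 0.5)
  sm <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sm), c(25L, 3L))
  expect_output(print(fit), "pooled R2")
  expect_output(summary(fit), "Winning combinations")
})

test_that("degenerate inputs are rejected", {
  fx <- .toy_regression(n = 12, seed = 43)
  expect_error(nested_cv(fx$X, rep(5, 12), model_spec("elasticnet"),
                         outer = "loo", inner_k = 3, seed = 1), "constant")
  expect_error(nested_cv(fx$X, fx$y[1:3], model_spec("elasticnet")), "nrow")
})
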