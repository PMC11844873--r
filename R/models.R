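# Model-family backends: a uniform fit/predict/importance surface over
# glmnet (elastic net), e1071 (linear-kernel SVM regression), randomForest,
# and xgboost (gradient boosting). Features are standardized by the CV
# harness, so backends never rescale internally.

#' Default hyperparameter grids per model family
#'
#' Compact, documented grids searched by the inner cross-validation loop:
#' elastic net over mixing ratio x regularization strength; linear SVM over
#' cost; random forest over the number of candidate variables per split;
#' gradient boosting over tree depth. All grids are overridable in
#' \code{\link{model_spec}}.
#'
#' @param family one of \code{"elasticnet"}, \code{"linear_svm"},
#'   \code{"random_forest"}, \code{"gradient_boosting"}.
#' @return list of named hyperparameter lists (one per grid point).
#' @export
default_grid <- function(family) {
  grids <- switch(
    family,
    elasticnet = expand.grid(alpha = c(0.1, 0.5, 0.9),
                             lambda = c(0.01, 0.1, 1, 10)),
    linear_svm = expand.grid(cost = c(0.01, 0.1, 1, 10)),
    random_forest = expand.grid(mtry_frac = c(1 / 3, 2 / 3),
                                ntree = 100),
    gradient_boosting = expand.grid(max_depth = c(2, 3), nrounds = 60,
                                    eta = 0.3),
    stop(sprintf("unknown model family '%s'", family))
  )
  lapply(seq_len(nrow(grids)), function(i) as.list(grids[i, , drop = FALSE]))
}

#' Specify a model family and its hyperparameter grid
#'
#' @param family model family name.
#' @param grid list of hyperparameter lists; defaults to
#'   \code{\link{default_grid}}.
#' @param seed integer seed used by the stochastic (tree) families.
#' @return object of class \code{model_spec}.
#' @export
model_spec <- function(family = c("elasticnet", "linear_svm",
                                  "random_forest", "gradient_boosting"),
                       grid = NULL, seed = 1L) {
  family <- match.arg(family)
  if (is.null(grid)) grid <- default_grid(family)
  stopifnot(length(grid) >= 1L)
  structure(list(family = family, grid = grid, seed = as.integer(seed)),
            class = "model_spec")
}

# fit one model; X numeric matrix (already standardized/imputed), y numeric
.fit_model <- function(family, params, X, y, seed) {
  switch(
    family,
    elasticnet = {
      fit <- glmnet::glmnet(X, y, alpha = params$alpha, standardize = FALSE)
      list(family = family, fit = fit, lambda = params$lambda)
    },
    linear_svm = {
      fit <- e1071::svm(X, y, type = "eps-regression", kernel = "linear",
                        cost = params$cost, scale = FALSE)
      list(family = family, fit = fit)
    },
    random_forest = {
      set.seed(seed)
      mtry <- max(1L, floor(params$mtry_frac * ncol(X)))
      fit <- randomForest::randomForest(X, y, ntree = params$ntree, mtry = mtry)
      list(family = family, fit = fit)
    },
    gradient_boosting = {
      fit <- xgboost::xgboost(
        X, y, nrounds = params$nrounds, max_depth = params$max_depth,
        learning_rate = params$eta, objective = "reg:squarederror",
        nthreads = 1L, seed = seed, verbosity = 0L)
      list(family = family, fit = fit)
    }
  )
}

.predict_model <- function(model, X) {
  switch(
    model$family,
    elasticnet = as.numeric(stats::predict(model$fit, newx = X, s = model$lambda)),
    linear_svm = as.numeric(stats::predict(model$fit, X)),
    random_forest = as.numeric(stats::predict(model$fit, X)),
    gradient_boosting = as.numeric(stats::predict(model$fit, X))
  )
}

# signed importance per feature: coefficients for the linear families,
# impurity importance signed by the univariate correlation with the target
# for the tree families
.importance_model <- function(model, X, y) {
  p <- ncol(X); nm <- colnames(X)
  out <- switch(
    model$family,
    elasticnet = {
      b <- as.numeric(stats::coef(model$fit, s = model$lambda))[-1L]
      b
    },
    linear_svm = {
      w <- as.numeric(t(model$fit$coefs) %*% model$fit$SV)
      w
    },
    random_forest = {
      imp <- randomForest::importance(model$fit)[, 1L]
      imp <- imp[match(nm, rownames(randomForest::importance(model$fit)))]
      imp[is.na(imp)] <- 0
      .sign_by_correlation(imp, X, y)
    },
    gradient_boosting = {
      it <- xgboost::xgb.importance(model = model$fit)
      imp <- rep(0, p)
      hit <- match(it$Feature, nm)
      imp[hit[!is.na(hit)]] <- it$Gain[!is.na(hit)]
      .sign_by_correlation(imp, X, y)
    }
  )
  names(out) <- nm
  out
}

# RMSE on a validation split for every grid point of one family; elastic net
# batches all lambdas of an alpha into a single path fit
.score_family <- function(family, grid, Xtr, ytr, Xva, yva, seed) {
  k <- length(grid)
  out <- numeric(k)
  if (family == "elasticnet") {
    alphas <- vapply(grid, `[[`, numeric(1), "alpha")
    lambdas <- vapply(grid, `[[`, numeric(1), "lambda")
    for (a in unique(alphas)) {
      rows <- which(alphas == a)
      fit <- glmnet::glmnet(Xtr, ytr, alpha = a, standardize = FALSE)
      P <- stats::predict(fit, newx = Xva, s = lambdas[rows])
      out[rows] <- sqrt(colMeans((yva - P)^2))
    }
  } else {
    for (i in seq_len(k)) {
      m <- .fit_model(family, grid[[i]], Xtr, ytr, seed)
      out[i] <- sqrt(mean((yva - .predict_model(m, Xva))^2))
    }
  }
  out
}

.sign_by_correlation <- function(imp, X, y) {
  sg <- vapply(seq_len(ncol(X)), function(j) {
    xj <- X[, j]
    if (stats::sd(xj) == 0 || stats::sd(y) == 0) return(1)
    s <- sign(stats::cor(xj, y))
    if (s == 0) 1 else s
  }, numeric(1))
  abs(imp) * sg
}
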