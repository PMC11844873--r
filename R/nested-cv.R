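# Nested cross-validation: a leave-one-out (or k-fold) outer loop estimates
# out-of-sample performance while an inner k-fold loop selects
# hyperparameters (or, in the joint scheme, the model x hyperparameters x
# parcellation combination) by lowest mean RMSE. All standardization and
# imputation is fit on training participants only.

# --- fold / seed plumbing ----------------------------------------------------

.make_folds <- function(n, k, seed) {
  set.seed(seed)
  sample(rep(seq_len(k), length.out = n))
}

.seed_stream <- function(master, n) {
  set.seed(master)
  sample.int(2147483646L, n)
}

# --- training-fold preprocessing --------------------------------------------

.preproc_fit <- function(X, continuous) {
  med <- apply(X, 2L, function(x) stats::median(x, na.rm = TRUE))
  med[!is.finite(med)] <- 0
  Ximp <- X
  for (j in seq_len(ncol(X))) Ximp[is.na(Ximp[, j]), j] <- med[j]
  ctr <- rep(0, ncol(X)); scl <- rep(1, ncol(X))
  if (any(continuous)) {
    ctr[continuous] <- colMeans(Ximp[, continuous, drop = FALSE])
    s <- apply(Ximp[, continuous, drop = FALSE], 2L, stats::sd)
    s[!is.finite(s) | s == 0] <- 1
    scl[continuous] <- s
  }
  list(median = med, center = ctr, scale = scl)
}

.preproc_apply <- function(pp, X) {
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- pp$median[j]
  X <- sweep(X, 2L, pp$center, "-")
  X <- sweep(X, 2L, pp$scale, "/")
  unclass(X)
}

.continuous_of <- function(X) {
  ct <- attr(X, "continuous")
  if (is.null(ct)) rep(TRUE, ncol(X)) else ct
}

# --- the shared engine -------------------------------------------------------

# X_list: named list of feature matrices (one per parcellation / feature set)
# combos: data.frame(set = name into X_list, family, param_id); specs: named
# list of model_spec keyed by family. Returns the fitted severity_cv.
.nested_cv_engine <- function(X_list, y, combos, specs, outer, inner_k, seed,
                              call = sys.call(-1)) {
  n <- length(y)
  if (!all(is.finite(y))) stop("targets must be finite")
  if (stats::sd(y) == 0) stop("constant targets: R2 undefined")
  outer_k <- if (identical(outer, "loo")) n else as.integer(outer)
  if (n < inner_k + 1L) stop("too few participants for the inner loop")
  fold_of <- if (identical(outer, "loo")) seq_len(n) else
    .make_folds(n, outer_k, .seed_stream(seed, 1L))
  seeds <- matrix(.seed_stream(seed + 1L, outer_k * (nrow(combos) + 2L)),
                  nrow = outer_k)

  preds <- rep(NA_real_, n)
  chosen <- vector("list", outer_k)
  imp_list <- vector("list", outer_k)

  for (f in seq_len(outer_k)) {
    te <- which(fold_of == f)
    tr <- setdiff(seq_len(n), te)
    inner_fold <- .make_folds(length(tr), inner_k, seeds[f, 1L])
    # mean RMSE across inner folds for every candidate combination;
    # preprocessing is fit per (feature set, inner fold) and shared across
    # families, and family scorers batch over their grids
    errs <- matrix(NA_real_, nrow(combos), inner_k)
    for (kf in seq_len(inner_k)) {
      itr <- tr[inner_fold != kf]; iva <- tr[inner_fold == kf]
      for (s in unique(combos$set)) {
        Xall <- X_list[[s]]
        pp <- .preproc_fit(Xall[itr, , drop = FALSE], .continuous_of(Xall))
        Xtr <- .preproc_apply(pp, Xall[itr, , drop = FALSE])
        Xva <- .preproc_apply(pp, Xall[iva, , drop = FALSE])
        for (fam in unique(combos$family[combos$set == s])) {
          rows <- which(combos$set == s & combos$family == fam)
          errs[rows, kf] <- .score_family(
            fam, specs[[fam]]$grid[combos$param_id[rows]],
            Xtr, y[itr], Xva, y[iva], seeds[f, 1L + rows[1L]])
        }
      }
    }
    rmse <- rowMeans(errs)
    best <- which.min(rmse)                    # ties: first in grid order
    cmb <- combos[best, ]
    params <- specs[[cmb$family]]$grid[[cmb$param_id]]
    Xall <- X_list[[cmb$set]]
    pp <- .preproc_fit(Xall[tr, , drop = FALSE], .continuous_of(Xall))
    Xtr <- .preproc_apply(pp, Xall[tr, , drop = FALSE])
    Xte <- .preproc_apply(pp, Xall[te, , drop = FALSE])
    m <- .fit_model(cmb$family, params, Xtr, y[tr], seeds[f, 1L + best])
    preds[te] <- .predict_model(m, Xte)
    imp_list[[f]] <- .importance_model(m, Xtr, y[tr])
    chosen[[f]] <- data.frame(fold = f, set = cmb$set, family = cmb$family,
                              inner_rmse = rmse[best],
                              params = I(list(params)),
                              stringsAsFactors = FALSE)
  }

  chosen <- do.call(rbind, chosen)
  met <- regression_metrics(y, preds)
  imp <- .median_importance(imp_list)

  # final refit on everyone with the modal winning combination, for predict()
  key <- paste(chosen$set, chosen$family,
               vapply(chosen$params, function(p) paste(unlist(p), collapse = ","),
                      character(1)))
  mode_row <- which(key == names(sort(table(key), decreasing = TRUE))[1L])[1L]
  fin_cmb <- chosen[mode_row, ]
  Xall <- X_list[[fin_cmb$set]]
  pp <- .preproc_fit(Xall, .continuous_of(Xall))
  Xs <- .preproc_apply(pp, Xall)
  fin <- .fit_model(fin_cmb$family, fin_cmb$params[[1L]], Xs, y,
                    seeds[1L, ncol(seeds)])

  structure(list(call = call, n = n, y = y, predictions = preds,
                 outer = outer, inner_k = inner_k, fold_of = fold_of,
                 chosen = chosen, metrics = met, importance = imp,
                 final = list(model = fin, preproc = pp, set = fin_cmb$set,
                              family = fin_cmb$family,
                              params = fin_cmb$params[[1L]]),
                 feature_sets = names(X_list), seed = seed),
            class = "severity_cv")
}

.median_importance <- function(imp_list) {
  feats <- unique(unlist(lapply(imp_list, names)))
  M <- sapply(imp_list, function(v) v[feats])
  if (is.null(dim(M))) M <- matrix(M, nrow = length(feats))
  rownames(M) <- feats
  med <- apply(M, 1L, function(x) stats::median(x, na.rm = TRUE))
  out <- data.frame(feature = feats, median_importance = med,
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$median_importance)), ]
  rownames(out) <- NULL
  out
}

# --- user-facing fitting functions ------------------------------------------

#' Nested cross-validation for one model family (per-combination scheme)
#'
#' The default evaluation scheme: each model family x parcellation
#' combination is evaluated separately. The outer loop (leave-one-out by
#' default) holds out one participant at a time; the inner k-fold loop on the
#' remaining participants selects the hyperparameter set with the lowest mean
#' RMSE; that set is refit on all training participants and predicts the
#' held-out one. Pooled out-of-fold predictions give R2 and RMSE.
#'
#' @param X a \code{\link{feature_matrix}} (participants x features).
#' @param y numeric target vector (MDS-UPDRS totals).
#' @param model a \code{\link{model_spec}}.
#' @param outer \code{"loo"} or an integer number of outer folds.
#' @param inner_k inner folds (default 10).
#' @param seed master seed; every stochastic step derives from it.
#' @return a \code{severity_cv} object; see \code{\link{severity_cv-methods}}.
#' @export
nested_cv <- function(X, y, model = model_spec("elasticnet"), outer = "loo",
                      inner_k = 10L, seed = 1L) {
  stopifnot(inherits(model, "model_spec"), is.matrix(X), nrow(X) == length(y))
  combos <- data.frame(set = "features", family = model$family,
                       param_id = seq_along(model$grid),
                       stringsAsFactors = FALSE)
  .nested_cv_engine(list(features = X), y, combos,
                    specs = stats::setNames(list(model), model$family),
                    outer = outer, inner_k = inner_k, seed = seed,
                    call = match.call())
}

#' Joint nested cross-validation over models and parcellations
#'
#' The alternative reporting scheme: per outer iteration the inner loop
#' searches jointly over model family x hyperparameters x parcellation and
#' the single winning combination predicts the held-out participant. With one
#' model and one parcellation this reduces exactly to \code{\link{nested_cv}}.
#'
#' @param X_list named list of \code{\link{feature_matrix}} objects, one per
#'   parcellation.
#' @param y numeric target vector.
#' @param models list of \code{\link{model_spec}} objects.
#' @param outer,inner_k,seed as in \code{\link{nested_cv}}.
#' @return a \code{severity_cv} object whose \code{chosen} table records the
#'   winning combination per outer fold.
#' @export
nested_cv_joint <- function(X_list, y, models, outer = "loo", inner_k = 10L,
                            seed = 1L) {
  stopifnot(is.list(X_list), length(X_list) >= 1L, !is.null(names(X_list)),
            is.list(models), length(models) >= 1L)
  fams <- vapply(models, function(m) m$family, character(1))
  if (anyDuplicated(fams)) stop("one model_spec per family")
  specs <- stats::setNames(models, fams)
  combos <- do.call(rbind, lapply(names(X_list), function(s) {
    do.call(rbind, lapply(fams, function(fm) {
      data.frame(set = s, family = fm,
                 param_id = seq_along(specs[[fm]]$grid),
                 stringsAsFactors = FALSE)
    }))
  }))
  .nested_cv_engine(X_list, y, combos, specs, outer = outer,
                    inner_k = inner_k, seed = seed, call = match.call())
}

#' Permutation-based chance level for the pooled R2
#'
#' Shuffles the targets and reruns nested cross-validation (5-fold outer and
#' 5-fold inner, elastic net — the fixed model/parcellation combination used
#' for chance-level estimation) for each permutation, yielding the null
#' distribution of out-of-sample R2. Features are never touched.
#'
#' @param X a \code{\link{feature_matrix}}.
#' @param y numeric targets.
#' @param n_permutations default 1000 (desk-scale runs use fewer).
#' @param seed master seed.
#' @param model fixed \code{\link{model_spec}} (default elastic net).
#' @return object of class \code{permutation_null}: list with \code{r2}
#'   (per-permutation pooled R2), \code{mean}, \code{q95},
#'   \code{n_permutations}.
#' @export
permutation_null <- function(X, y, n_permutations = 1000L, seed = 1L,
                             model = model_spec("elasticnet")) {
  if (n_permutations < 1L) stop("need at least one permutation")
  if (length(y) < 10L) stop("need at least 10 participants")
  perm_seeds <- .seed_stream(seed, n_permutations)
  r2 <- vapply(seq_len(n_permutations), function(p) {
    set.seed(perm_seeds[p])
    yp <- sample(y)
    fit <- nested_cv(X, yp, model = model, outer = 5L, inner_k = 5L,
                     seed = perm_seeds[p])
    fit$metrics$r2
  }, numeric(1))
  structure(list(r2 = r2, mean = mean(r2),
                 q95 = as.numeric(stats::quantile(r2, 0.95)),
                 n_permutations = n_permutations, seed = seed),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf("<permutation_null> %d permutations: mean R2 = %.3f, 95th pct = %.3f\n",
              x$n_permutations, x$mean, x$q95))
  invisible(x)
}

# --- metrics -----------------------------------------------------------------

#' Regression metrics on pooled predictions
#'
#' @param y_true,y_pred equal-length finite numeric vectors; \code{y_true}
#'   must be non-constant for R2.
#' @return list with \code{r2} (1 - SSE/SST) and \code{rmse}.
#' @export
regression_metrics <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 2L,
            all(is.finite(y_true)), all(is.finite(y_pred)))
  sst <- sum((y_true - mean(y_true))^2)
  if (sst == 0) stop("constant y_true: R2 undefined")
  list(r2 = 1 - sum((y_true - y_pred)^2) / sst,
       rmse = sqrt(mean((y_true - y_pred)^2)))
}

#' Post-hoc severity classification metrics
#'
#' Thresholds true totals and continuous predictions at the severity cut-off
#' (totals at or above the threshold are the high-severity positive class),
#' and summarizes the resulting 2x2 table. AUC is the rank statistic of the
#' continuous predictions against the thresholded truths (midrank ties).
#'
#' @param y_true numeric true totals.
#' @param y_pred continuous predicted totals.
#' @param threshold numeric or a \code{\link{severity_threshold}}.
#' @return list with \code{auc}, \code{ppv}, \code{npv}, \code{specificity},
#'   \code{sensitivity} and the \code{confusion} counts.
#' @export
classification_metrics <- function(y_true, y_pred, threshold) {
  thr <- if (inherits(threshold, "severity_threshold")) threshold$value else
    as.numeric(threshold)
  truth <- y_true >= thr
  if (all(truth) || !any(truth))
    stop("both severity classes must be present after thresholding")
  pred <- y_pred >= thr
  tp <- sum(pred & truth); fp <- sum(pred & !truth)
  tn <- sum(!pred & !truth); fn <- sum(!pred & truth)
  r <- rank(y_pred)                        # midranks
  n1 <- sum(truth); n0 <- sum(!truth)
  auc <- (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  list(auc = auc,
       ppv = tp / (tp + fp), npv = tn / (tn + fn),
       specificity = tn / (tn + fp), sensitivity = tp / (tp + fn),
       confusion = c(TP = tp, FP = fp, TN = tn, FN = fn))
}

#' Median feature importance across outer folds
#'
#' For the linear families the per-fold importance is the signed model
#' coefficient; for the tree families it is the impurity importance with the
#' sign of the feature's univariate linear correlation with the target. The
#' per-feature median across outer folds is reported, sorted by magnitude.
#'
#' @param object a \code{severity_cv} fit.
#' @return data.frame with \code{feature} and \code{median_importance}.
#' @export
feature_importance <- function(object) {
  stopifnot(inherits(object, "severity_cv"))
  object$importance
}

# --- severity_cv methods -----------------------------------------------------

#' Methods for severity_cv fits
#'
#' A \code{severity_cv} object holds the pooled out-of-fold predictions of a
#' nested cross-validation run, the per-fold winning combinations, pooled R2
#' and RMSE, the per-feature median importance, and a final model refit on
#' all participants with the modal winning hyperparameters (used by
#' \code{predict}).
#'
#' @param x,object a \code{severity_cv} fit.
#' @param newdata feature matrix with the training columns.
#' @param nsim,seed,... standard method arguments.
#' @name severity_cv-methods
NULL

#' @rdname severity_cv-methods
#' @export
print.severity_cv <- function(x, ...) {
  cat(sprintf("<severity_cv> %s | outer: %s, inner: %d-fold | n = %d\n",
              paste(unique(x$chosen$family), collapse = "/"),
              if (identical(x$outer, "loo")) "leave-one-out" else
                sprintf("%d-fold", x$outer),
              x$inner_k, x$n))
  cat(sprintf("  pooled R2 = %.4f, RMSE = %.4f\n", x$metrics$r2, x$metrics$rmse))
  invisible(x)
}

#' @rdname severity_cv-methods
#' @export
summary.severity_cv <- function(object, ...) {
  print(object)
  cat("\nWinning combinations across outer folds:\n")
  key <- paste(object$chosen$set, object$chosen$family)
  print(sort(table(key), decreasing = TRUE))
  cat("\nTop features by |median importance|:\n")
  print(utils::head(object$importance, 10), row.names = FALSE)
  invisible(object)
}

#' @rdname severity_cv-methods
#' @export
coef.severity_cv <- function(object, ...) {
  stats::setNames(object$importance$median_importance, object$importance$feature)
}

#' @rdname severity_cv-methods
#' @export
predict.severity_cv <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$predictions)
  Xs <- .preproc_apply(object$final$preproc, as.matrix(newdata))
  .predict_model(object$final$model, Xs)
}

#' @rdname severity_cv-methods
#' @export
fitted.severity_cv <- function(object, ...) object$predictions

#' @rdname severity_cv-methods
#' @export
residuals.severity_cv <- function(object, ...) object$y - object$predictions

#' @rdname severity_cv-methods
#' @export
plot.severity_cv <- function(x, ...) {
  graphics::plot(x$y, x$predictions,
                 xlab = "observed MDS-UPDRS total",
                 ylab = "out-of-fold prediction",
                 main = sprintf("pooled R2 = %.3f", x$metrics$r2), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' @rdname severity_cv-methods
#' @export
simulate.severity_cv <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  s <- stats::sd(residuals(object))
  out <- replicate(nsim, object$predictions + stats::rnorm(object$n, 0, s))
  as.data.frame(out)
}
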