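# End-to-end orchestration: the default analysis workflow and its named
# variants (feature-computation toggles C.1/C.2, input-feature ablations
# D.1-D.4, evaluation-scheme alternatives E.1/E.2), plus cross-workflow
# comparison against the 0.15 comparability margin.

#' Resolve a workflow variant into a consistent configuration
#'
#' Each variant implies toggles on top of the default workflow: \code{C1} =
#' no z-scoring, \code{C2} = ALFF instead of fALFF, \code{D1} = drop the
#' dominant-side feature, \code{D2} = drop the baseline score, \code{D3} =
#' clinical/demographic features only, \code{D4} = imaging features only,
#' \code{E1} = joint nested cross-validation over model x hyperparameters x
#' parcellation, \code{E2} = report a single fixed model x parcellation.
#' \code{A1} is the default pipeline on an alternative cohort (supply it via
#' \code{run_workflow(cohort = ...)}). Explicit arguments that contradict
#' the variant's implied toggles are an error.
#'
#' @param variant one of \code{"default"}, \code{"A1"}, \code{"C1"},
#'   \code{"C2"}, \code{"D1"}, \code{"D2"}, \code{"D3"}, \code{"D4"},
#'   \code{"E1"}, \code{"E2"}.
#' @param feature_type \code{"falff"}, \code{"reho"} or \code{"alff"}.
#' @param zscore use participant-level z-scored maps.
#' @param feature_set see \code{\link{encode_features}}.
#' @param scheme \code{"per_combo"}, \code{"joint"} or \code{"fixed"}.
#' @param families model families to evaluate.
#' @param parcellations parcellation names to evaluate (NULL = all in the
#'   study).
#' @param fixed_family,fixed_parcellation the single combination reported
#'   under \code{scheme = "fixed"} (variant E2).
#' @param timepoints subset of \code{c("Baseline", "Year1", "Year2",
#'   "Year4")}.
#' @param outer,inner_k cross-validation geometry (defaults: leave-one-out
#'   outer, 10-fold inner).
#' @param seed master seed.
#' @return a \code{workflow_config} list.
#' @export
workflow_config <- function(variant = "default",
                            feature_type = NULL, zscore = NULL,
                            feature_set = NULL, scheme = NULL,
                            families = c("elasticnet", "linear_svm",
                                         "random_forest", "gradient_boosting"),
                            parcellations = NULL,
                            fixed_family = "elasticnet",
                            fixed_parcellation = "primary",
                            timepoints = c("Baseline", "Year1", "Year2", "Year4"),
                            outer = "loo", inner_k = 10L, seed = 1L) {
  variants <- list(
    default = list(), A1 = list(),
    C1 = list(zscore = FALSE),
    C2 = list(feature_type = "alff"),
    D1 = list(feature_set = "no_side"),
    D2 = list(feature_set = "no_baseline_score"),
    D3 = list(feature_set = "clinical_only"),
    D4 = list(feature_set = "imaging_only"),
    E1 = list(scheme = "joint"),
    E2 = list(scheme = "fixed"))
  if (!variant %in% names(variants)) stop(sprintf("unknown variant '%s'", variant))
  implied <- variants[[variant]]
  pick <- function(name, default) {
    user <- get(name)
    if (!is.null(implied[[name]])) {
      if (!is.null(user) && !identical(user, implied[[name]]))
        stop(sprintf("variant %s implies %s = %s; contradictory value given",
                     variant, name, implied[[name]]))
      implied[[name]]
    } else if (!is.null(user)) user else default
  }
  cfg <- list(variant = variant,
              feature_type = pick("feature_type", "falff"),
              zscore = pick("zscore", TRUE),
              feature_set = pick("feature_set", "all"),
              scheme = pick("scheme", "per_combo"),
              families = families, parcellations = parcellations,
              fixed_family = fixed_family,
              fixed_parcellation = fixed_parcellation,
              timepoints = timepoints, outer = outer, inner_k = inner_k,
              seed = as.integer(seed))
  class(cfg) <- "workflow_config"
  cfg
}

# pick the study's regional-feature block matching the config
.study_features <- function(study, cfg) {
  key <- switch(cfg$feature_type,
                falff = if (cfg$zscore) "falff" else "falff_nz",
                alff = "alff",
                reho = "reho")
  if (cfg$feature_type %in% c("alff", "reho") && !cfg$zscore)
    stop("non-z-scored features are only stored for fALFF in this study")
  fb <- study$features[[key]]
  if (is.null(fb))
    stop(sprintf("study does not carry '%s' features; regenerate with compute_reho = TRUE",
                 key))
  if (!is.null(cfg$parcellations)) fb <- fb[cfg$parcellations]
  fb
}

#' Run a workflow end to end on a synthetic study
#'
#' Assembles per-time-point cohorts (follow-up visits matched inside the
#' 365/730/1460 +/- 60 day windows), encodes clinical, demographic and
#' regional imaging features, evaluates the configured model families and
#' parcellations under the configured nested cross-validation scheme, and
#' reports pooled R2/RMSE per combination, the severity threshold, post-hoc
#' classification metrics and median feature importance for the
#' best-performing combination, plus an FD-based QC block.
#'
#' @param study a \code{\link{synth_study}} (carries precomputed regional
#'   feature maps generated by the package's own imaging pipeline).
#' @param config a \code{\link{workflow_config}}, or a variant name.
#' @param cohort optional replacement cohort table (variant A1).
#' @param ... passed to \code{\link{workflow_config}} when \code{config} is a
#'   variant name.
#' @return object of class \code{run_report}.
#' @export
run_workflow <- function(study, config = "default", cohort = NULL, ...) {
  stopifnot(inherits(study, "synth_study"))
  if (is.character(config)) config <- workflow_config(config, ...)
  stopifnot(inherits(config, "workflow_config"))
  cohort <- if (is.null(cohort)) study$cohort else cohort
  fb <- .study_features(study, config)

  # ON-medication filter mirrors the PAG_NAME != "NUPDRS3" rule
  cohort <- cohort[cohort$PAG_NAME != "NUPDRS3", , drop = FALSE]
  bl <- cohort[cohort$EVENT_ID == "BL", , drop = FALSE]
  bl <- bl[order(bl$PATNO), , drop = FALSE]
  totals_bl <- cohort_totals(bl)
  names(totals_bl) <- as.character(bl$PATNO)
  fu <- match_followups(cohort)

  # severity threshold: mean of the four per-time-point medians
  totals_tp <- list(Baseline = unname(totals_bl))
  fu_totals <- list()
  for (tp in names(fu)) {
    m <- fu[[tp]]
    key <- paste(cohort$PATNO, cohort$EVENT_ID)
    rows <- cohort[match(paste(m$PATNO, m$EVENT_ID), key), , drop = FALSE]
    fu_totals[[tp]] <- stats::setNames(cohort_totals(rows), as.character(m$PATNO))
    totals_tp[[tp]] <- unname(fu_totals[[tp]])
  }
  thr <- severity_threshold(totals_tp)

  row_of <- match(bl$PATNO, sort(unique(study$cohort$PATNO[study$cohort$EVENT_ID == "BL"])))
  results <- list(); best <- list(); metrics_rows <- list()
  for (tp in intersect(config$timepoints, c("Baseline", names(fu)))) {
    if (tp == "Baseline") {
      ids <- as.character(bl$PATNO); y <- unname(totals_bl)
      base_tot <- NULL
    } else {
      ids <- names(fu_totals[[tp]]); y <- unname(fu_totals[[tp]])
      base_tot <- unname(totals_bl[ids])
    }
    sel <- match(ids, as.character(bl$PATNO))
    X_list <- lapply(fb, function(M) {
      img <- M[row_of[sel], , drop = FALSE]
      encode_features(bl[sel, , drop = FALSE], feature_set = config$feature_set,
                      imaging = img, baseline_total = base_tot)
    })
    fit_tp <- .evaluate_timepoint(X_list, y, config)
    results[[tp]] <- fit_tp
    metrics_rows[[tp]] <- fit_tp$table
    best[[tp]] <- fit_tp$best
  }

  metrics <- do.call(rbind, lapply(names(metrics_rows), function(tp)
    cbind(timepoint = tp, feature_type = config$feature_type,
          metrics_rows[[tp]], stringsAsFactors = FALSE)))

  classification <- lapply(best, function(b) {
    tryCatch(classification_metrics(b$fit$y, b$fit$predictions, thr),
             error = function(e) NULL)
  })

  structure(list(variant = config$variant, config = config,
                 threshold = thr, metrics = metrics,
                 best = best, classification = classification,
                 qc = list(mean_fd = study$fd,
                           flagged = which(study$fd > 0.55)),
                 n_per_timepoint = vapply(totals_tp, length, 1L),
                 package_version = as.character(utils::packageVersion("parksev")),
                 seed = config$seed),
            class = "run_report")
}

# evaluate one time point under the configured scheme
.evaluate_timepoint <- function(X_list, y, config) {
  specs <- lapply(config$families, model_spec)
  names(specs) <- config$families
  if (config$scheme == "per_combo") {
    rows <- list(); fits <- list()
    for (pn in names(X_list)) for (fam in config$families) {
      fit <- nested_cv(X_list[[pn]], y, model = specs[[fam]],
                       outer = config$outer, inner_k = config$inner_k,
                       seed = config$seed)
      rows[[length(rows) + 1L]] <- data.frame(
        family = fam, parcellation = pn, r2 = fit$metrics$r2,
        rmse = fit$metrics$rmse, stringsAsFactors = FALSE)
      fits[[paste(fam, pn)]] <- fit
    }
    tab <- do.call(rbind, rows)
    bi <- which.max(tab$r2)
    list(table = tab, fits = fits,
         best = list(family = tab$family[bi], parcellation = tab$parcellation[bi],
                     fit = fits[[paste(tab$family[bi], tab$parcellation[bi])]]))
  } else if (config$scheme == "joint") {
    fit <- nested_cv_joint(X_list, y, models = unname(specs),
                           outer = config$outer, inner_k = config$inner_k,
                           seed = config$seed)
    tab <- data.frame(family = "joint", parcellation = "joint",
                      r2 = fit$metrics$r2, rmse = fit$metrics$rmse,
                      stringsAsFactors = FALSE)
    list(table = tab, fits = list(joint = fit),
         best = list(family = "joint", parcellation = "joint", fit = fit))
  } else {                                   # fixed: E2 single combination
    fam <- config$fixed_family; pn <- config$fixed_parcellation
    if (!pn %in% names(X_list)) stop(sprintf("parcellation '%s' not available", pn))
    fit <- nested_cv(X_list[[pn]], y, model = specs[[fam]] %||% model_spec(fam),
                     outer = config$outer, inner_k = config$inner_k,
                     seed = config$seed)
    tab <- data.frame(family = fam, parcellation = pn, r2 = fit$metrics$r2,
                      rmse = fit$metrics$rmse, stringsAsFactors = FALSE)
    list(table = tab, fits = stats::setNames(list(fit), paste(fam, pn)),
         best = list(family = fam, parcellation = pn, fit = fit))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> variant %s, feature %s, scheme %s\n",
              x$variant, x$config$feature_type, x$config$scheme))
  cat(sprintf("  severity threshold = %.4g\n", x$threshold$value))
  for (tp in names(x$best)) {
    b <- x$best[[tp]]
    cat(sprintf("  %s: best %s / %s, R2 = %.3f, RMSE = %.3f (n = %d)\n",
                tp, b$family, b$parcellation, b$fit$metrics$r2,
                b$fit$metrics$rmse, b$fit$n))
  }
  invisible(x)
}

#' Compare workflow reports against a reference
#'
#' Per time point, the difference of the best-combination R2 from the
#' reference report's; differences larger in magnitude than the margin are
#' flagged, as are best R2 values that do not beat chance (non-positive, or
#' below the permutation null's 95th percentile when a null is supplied).
#'
#' @param reports named list of \code{run_report}s; the first is the
#'   reference unless \code{reference} names another.
#' @param margin comparability margin on R2 (default 0.15).
#' @param reference name of the reference report.
#' @param null optional \code{\link{permutation_null}}.
#' @return data.frame with one row per report x time point.
#' @export
compare_workflows <- function(reports, margin = 0.15,
                              reference = names(reports)[1L], null = NULL) {
  stopifnot(is.list(reports), length(reports) >= 1L, !is.null(names(reports)))
  ref <- reports[[reference]]
  tps <- names(ref$best)
  rows <- list()
  for (nm in names(reports)) {
    rp <- reports[[nm]]
    if (!identical(names(rp$best), tps))
      stop("reports do not share time points")
    for (tp in tps) {
      r2 <- rp$best[[tp]]$fit$metrics$r2
      d <- r2 - ref$best[[tp]]$fit$metrics$r2
      chance <- r2 <= 0 || (!is.null(null) && r2 <= null$q95)
      rows[[length(rows) + 1L]] <- data.frame(
        report = nm, timepoint = tp, r2 = r2, delta_r2 = d,
        flag_margin = abs(d) > margin, flag_chance = chance,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Read a workflow configuration from YAML
#'
#' The YAML file holds the arguments of \code{\link{workflow_config}} (e.g.
#' \code{variant}, \code{feature_type}, \code{families}, \code{seed});
#' variant/toggle contradictions are rejected exactly as from R.
#'
#' @param path YAML file path.
#' @return a \code{workflow_config}.
#' @export
read_workflow_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(workflow_config))
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop(sprintf("unknown config field(s): %s", paste(bad, collapse = ", ")))
  if (!is.null(cfg$families)) cfg$families <- as.character(cfg$families)
  if (!is.null(cfg$timepoints)) cfg$timepoints <- as.character(cfg$timepoints)
  do.call(workflow_config, cfg)
}

#' Write a run report to JSON + TSV
#'
#' @param report a \code{run_report}.
#' @param dir output directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(report$metrics, file.path(dir, "metrics.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  js <- list(variant = report$variant,
             threshold = report$threshold$value,
             medians = report$threshold$medians,
             n_per_timepoint = as.list(report$n_per_timepoint),
             classification = report$classification,
             qc = list(mean_fd_mean = mean(report$qc$mean_fd),
                       n_flagged = length(report$qc$flagged)),
             package_version = report$package_version,
             seed = report$seed)
  jsonlite::write_json(js, file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  for (tp in names(report$best)) {
    imp <- report$best[[tp]]$fit$importance
    utils::write.table(imp, file.path(dir, sprintf("importance_%s.tsv", tp)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}
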