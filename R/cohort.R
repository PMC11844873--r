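#' MDS-UPDRS total score for one visit row
#'
#' Sum of parts Ia (rater, NP1RTOT), Ib (patient questionnaire, NP1PTOT), II
#' (NP2TOT), III (NP3TOT) and IV (NP4TOT). Missing NP4TOT is treated as 0;
#' any other missing part is an error naming the offending row.
#'
#' @param row one-row data.frame (or list) with the five part columns.
#' @return non-negative total score.
#' @export
total_updrs <- function(row) {
  parts <- c("NP1RTOT", "NP1PTOT", "NP2TOT", "NP3TOT")
  vals <- vapply(parts, function(p) {
    v <- row[[p]]
    if (is.null(v) || length(v) != 1L || is.na(v))
      stop(sprintf("missing mandatory part %s in row %s", p,
                   paste(row[["PATNO"]], row[["EVENT_ID"]], sep = "/")))
    as.numeric(v)
  }, numeric(1))
  np4 <- row[["NP4TOT"]]
  np4 <- if (is.null(np4) || length(np4) != 1L || is.na(np4)) 0 else as.numeric(np4)
  sum(vals) + np4
}

#' Totals for every row of a cohort table
#'
#' @param cohort data.frame with one row per (participant, visit).
#' @return numeric vector of totals, NP4TOT missing treated as 0.
#' @export
cohort_totals <- function(cohort) {
  vapply(seq_len(nrow(cohort)), function(i) total_updrs(cohort[i, ]), numeric(1))
}

#' Match follow-up visits to longitudinal time points
#'
#' A follow-up visit matches time point Y iff its date lies within
#' \code{tolerance} days of baseline date + target_Y. Among multiple matches
#' the tie-break applies (closest to the target by default; exact ties and
#' the \code{"earliest"} policy take the earliest visit). Participants
#' without a match are excluded from that time point.
#'
#' @param cohort data.frame with columns PATNO, EVENT_ID, INFODT (ISO-8601).
#'   Baseline rows carry EVENT_ID \code{"BL"}.
#' @param targets named numeric vector of day offsets
#'   (default \code{c(Year1 = 365, Year2 = 730, Year4 = 1460)}).
#' @param tolerance window half-width in days (default 60).
#' @param tie_break \code{"closest_to_target"} or \code{"earliest"}.
#' @return named list, one data.frame per time point with columns PATNO,
#'   EVENT_ID, INFODT, days_from_baseline.
#' @export
match_followups <- function(cohort,
                            targets = c(Year1 = 365, Year2 = 730, Year4 = 1460),
                            tolerance = 60,
                            tie_break = c("closest_to_target", "earliest")) {
  tie_break <- match.arg(tie_break)
  stopifnot(tolerance > 0)
  dates <- as.Date(as.character(cohort$INFODT), format = "%Y-%m-%d")
  if (anyNA(dates)) stop("unparseable visit dates in INFODT (need ISO-8601)")
  cohort$INFODT <- format(dates)
  bl <- cohort[cohort$EVENT_ID == "BL", ]
  if (anyDuplicated(bl$PATNO)) stop("multiple baseline rows for a participant")
  bl_date <- as.Date(bl$INFODT); names(bl_date) <- as.character(bl$PATNO)
  out <- list()
  for (tp in names(targets)) {
    rows <- list()
    for (p in bl$PATNO) {
      cand <- cohort[cohort$PATNO == p & cohort$EVENT_ID != "BL", , drop = FALSE]
      if (nrow(cand) == 0L) next
      days <- as.numeric(as.Date(cand$INFODT) - bl_date[as.character(p)])
      off <- abs(days - targets[[tp]])
      ok <- off <= tolerance
      if (!any(ok)) next
      cand <- cand[ok, , drop = FALSE]; days <- days[ok]; off <- off[ok]
      pick <- if (tie_break == "earliest") which.min(days) else {
        best <- which(off == min(off))
        best[which.min(days[best])]       # exact distance tie -> earliest
      }
      rows[[length(rows) + 1L]] <- data.frame(
        PATNO = p, EVENT_ID = cand$EVENT_ID[pick], INFODT = cand$INFODT[pick],
        days_from_baseline = days[pick], stringsAsFactors = FALSE)
    }
    out[[tp]] <- if (length(rows)) do.call(rbind, rows) else
      data.frame(PATNO = character(0), EVENT_ID = character(0),
                 INFODT = character(0), days_from_baseline = numeric(0))
  }
  out
}

#' Documented categorical code map for clinical/demographic encoding
#'
#' There is no canonical character encoding for these fields; this map is a
#' documented, overridable convention. Binary indicators encode sex (male =
#' 1), handedness (right = 1), dominant symptom side (right = 1; left and
#' symmetric = 0); race and ethnicity use small integer codes.
#'
#' @return named list of named numeric vectors.
#' @export
default_code_map <- function() {
  list(
    SEX = c(M = 1, F = 0),
    HANDED = c(right = 1, left = 0, mixed = 0),
    DOMSIDE = c(right = 1, left = 0, symmetric = 0),
    RACE = c(white = 0, black = 1, asian = 2, other = 3),
    ETHNICITY = c(not_hispanic = 0, hispanic = 1)
  )
}

#' Encode clinical, demographic and imaging features into a model matrix
#'
#' Builds the participants x features matrix used by the models. Clinical
#' features: disease duration, symptom duration, dominant symptom side, GDS,
#' MoCA, and presence of tremor / rigidity / postural instability at
#' baseline. Demographic features: age, sex, ethnicity, race, handedness,
#' years of education. The baseline MDS-UPDRS total is added when supplied
#' (i.e. when predicting follow-up outcomes). \code{feature_set} variants
#' drop the columns their names imply, mirroring the input-feature ablation
#' workflows (\code{no_side} = D.1, \code{no_baseline_score} = D.2,
#' \code{clinical_only} = D.3, \code{imaging_only} = D.4).
#'
#' @param cohort data.frame, one row per participant (baseline rows).
#' @param feature_set one of \code{"all"}, \code{"no_side"},
#'   \code{"no_baseline_score"}, \code{"clinical_only"}, \code{"imaging_only"}.
#' @param imaging optional participants x regions matrix of regional imaging
#'   features (rows aligned with \code{cohort}).
#' @param baseline_total optional numeric vector of baseline totals (added as
#'   feature \code{baseline_updrs} unless the feature set drops it).
#' @param code_map categorical code map; see \code{\link{default_code_map}}.
#' @return numeric matrix with attributes \code{provenance} (one of
#'   \code{imaging}, \code{clinical}, \code{demographic},
#'   \code{baseline_score} per column), \code{continuous} (logical per
#'   column) and \code{code_map}.
#' @export
encode_features <- function(cohort,
                            feature_set = c("all", "no_side",
                                            "no_baseline_score",
                                            "clinical_only", "imaging_only"),
                            imaging = NULL, baseline_total = NULL,
                            code_map = default_code_map()) {
  feature_set <- match.arg(feature_set)
  n <- nrow(cohort)
  code <- function(col) {
    map <- code_map[[col]]
    v <- as.character(cohort[[col]])
    bad <- !v %in% names(map)
    if (any(bad))
      stop(sprintf("unknown value(s) %s in column %s",
                   paste(unique(v[bad]), collapse = ", "), col))
    unname(map[v])
  }
  cols <- list(); prov <- character(0); cont <- logical(0)
  add <- function(name, values, provenance, continuous) {
    cols[[name]] <<- as.numeric(values)
    prov <<- c(prov, provenance); cont <<- c(cont, continuous)
  }
  if (feature_set != "imaging_only") {
    add("age", cohort$AGE, "demographic", TRUE)
    add("sex_male", code("SEX"), "demographic", FALSE)
    add("ethnicity", code("ETHNICITY"), "demographic", FALSE)
    add("race", code("RACE"), "demographic", FALSE)
    add("handed_right", code("HANDED"), "demographic", FALSE)
    add("education_years", cohort$EDUCYRS, "demographic", TRUE)
    add("disease_duration", cohort$DXDUR, "clinical", TRUE)
    add("symptom_duration", cohort$SYMPDUR, "clinical", TRUE)
    if (feature_set != "no_side")
      add("dominant_side_right", code("DOMSIDE"), "clinical", FALSE)
    add("gds", cohort$GDS, "clinical", TRUE)
    add("moca", cohort$MOCA, "clinical", TRUE)
    add("tremor", as.numeric(cohort$TREMOR != 0), "clinical", FALSE)
    add("rigidity", as.numeric(cohort$RIGIDITY != 0), "clinical", FALSE)
    add("postural_instability", as.numeric(cohort$POSTINST != 0), "clinical", FALSE)
    if (!is.null(baseline_total) && feature_set != "no_baseline_score")
      add("baseline_updrs", baseline_total, "baseline_score", TRUE)
  }
  if (feature_set != "clinical_only" && !is.null(imaging)) {
    imaging <- as.matrix(imaging)
    stopifnot(nrow(imaging) == n)
    for (j in seq_len(ncol(imaging)))
      add(colnames(imaging)[j], imaging[, j], "imaging", TRUE)
  }
  if (feature_set == "imaging_only" && is.null(imaging))
    stop("feature_set = 'imaging_only' requires an imaging matrix")
  X <- do.call(cbind, cols)
  rownames(X) <- as.character(cohort$PATNO)
  if (anyDuplicated(colnames(X))) stop("duplicate feature names")
  feature_matrix(X, provenance = prov, continuous = cont, code_map = code_map)
}

#' Construct a feature matrix with provenance metadata
#'
#' @param X numeric matrix, participants x features.
#' @param provenance character per column.
#' @param continuous logical per column (continuous columns are standardized
#'   inside training folds; indicators pass through raw).
#' @param code_map the categorical code map used, for provenance.
#' @return the matrix with class \code{feature_matrix} and metadata
#'   attributes.
#' @export
feature_matrix <- function(X, provenance, continuous, code_map = NULL) {
  stopifnot(is.matrix(X), length(provenance) == ncol(X),
            length(continuous) == ncol(X), !is.null(colnames(X)))
  structure(X, provenance = provenance, continuous = continuous,
            code_map = code_map, class = c("feature_matrix", class(X)))
}

#' @export
`[.feature_matrix` <- function(x, i, j, ..., drop = FALSE) {
  prov <- attr(x, "provenance"); cont <- attr(x, "continuous")
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) {
    keep <- match(colnames(out), colnames(x))
    out <- feature_matrix(out, provenance = prov[keep],
                          continuous = cont[keep],
                          code_map = attr(x, "code_map"))
  }
  out
}

#' Severity threshold from longitudinal score distributions
#'
#' The high-vs-low severity cut-off: the arithmetic mean of the median
#' MDS-UPDRS total at each of the four time points (baseline and three
#' follow-ups). Medians of even-length samples are the mean of the central
#' pair.
#'
#' @param totals_by_timepoint list of 4 nonempty numeric vectors.
#' @return object of class \code{severity_threshold}: list with \code{value}
#'   and \code{medians}.
#' @export
severity_threshold <- function(totals_by_timepoint) {
  stopifnot(is.list(totals_by_timepoint), length(totals_by_timepoint) == 4L)
  if (any(vapply(totals_by_timepoint, length, 1L) == 0L))
    stop("every time point needs at least one score")
  med <- vapply(totals_by_timepoint, stats::median, numeric(1))
  structure(list(value = mean(med), medians = med),
            class = "severity_threshold")
}

#' @export
print.severity_threshold <- function(x, ...) {
  cat(sprintf("<severity_threshold> %.4g (medians: %s)\n", x$value,
              paste(signif(x$medians, 4), collapse = ", ")))
  invisible(x)
}

#' Read / write cohort tables
#'
#' Cohort tables are TSVs with PPMI-style column names (PATNO, EVENT_ID,
#' INFODT as ISO-8601 dates, NP1RTOT, NP1PTOT, NP2TOT, NP3TOT, NP4TOT, and
#' clinical/demographic columns).
#'
#' @param path file path.
#' @export
read_cohort <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    na.strings = c("NA", ""))
}

#' @rdname read_cohort
#' @param cohort data.frame to write.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
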