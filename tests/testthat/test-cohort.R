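test_that("total score sums the five parts with missing NP4 treated as zero", {
  expect_equal(total_updrs(list(NP1RTOT = 5, NP1PTOT = 4, NP2TOT = 10,
                                NP3TOT = 20, NP4TOT = NA)), 39)
  expect_equal(total_updrs(list(NP1RTOT = 0, NP1PTOT = 0, NP2TOT = 0,
                                NP3TOT = 0, NP4TOT = 0)), 0)
  expect_equal(total_updrs(list(NP1RTOT = 3, NP1PTOT = 2, NP2TOT = 8,
                                NP3TOT = 15, NP4TOT = 4)), 32)
  expect_error(total_updrs(list(PATNO = 7, EVENT_ID = "BL", NP1RTOT = 1,
                                NP1PTOT = NA, NP2TOT = 2, NP3TOT = 3)),
               "NP1PTOT")
})

test_that("follow-up matching respects the 60-day windows and tie-breaks", {
  mk <- function(days) data.frame(
    PATNO = 1, EVENT_ID = c("BL", sprintf("V%02d", seq_along(days))),
    INFODT = format(as.Date("2020-01-01") + c(0, days)),
    stringsAsFactors = FALSE)
  # +370 days matches Year 1; +430 does not (window ends at 425)
  expect_equal(nrow(match_followups(mk(370))$Year1), 1)
  expect_equal(match_followups(mk(370))$Year1$days_from_baseline, 370)
  expect_equal(nrow(match_followups(mk(430))$Year1), 0)
  # equidistant +350 / +380: exact tie resolves to the earliest visit
  tie <- match_followups(mk(c(350, 380)))$Year1
  expect_equal(tie$days_from_baseline, 350)
  # closest-to-target picks +380 over +320
  closest <- match_followups(mk(c(320, 380)))$Year1
  expect_equal(closest$days_from_baseline, 380)
  # earliest policy picks +320
  earliest <- match_followups(mk(c(320, 380)), tie_break = "earliest")$Year1
  expect_equal(earliest$days_from_baseline, 320)
  expect_error(match_followups(data.frame(PATNO = 1, EVENT_ID = "BL",
                                          INFODT = "not-a-date")),
               "dates")
})

test_that("time-point cohorts are subsets of baseline and independent of later matches", {
  set.seed(51)
  st <- synth_cohort(feature_matrix(matrix(rnorm(40 * 3), 40,
                                           dimnames = list(NULL, paste0("f", 1:3))),
                                    rep("imaging", 3), rep(TRUE, 3)),
                     n_baseline = 40, seed = 3)
  fu <- match_followups(st$cohort)
  bl_ids <- st$cohort$PATNO[st$cohort$EVENT_ID == "BL"]
  for (tp in names(fu)) expect_true(all(fu[[tp]]$PATNO %in% bl_ids))
  expect_equal(sort(fu$Year1$PATNO), st$truth$retained$Year1)
  expect_equal(sort(fu$Year4$PATNO), st$truth$retained$Year4)
})

test_that("feature encoding matches a hand-written expected matrix", {
  toy <- data.frame(
    PATNO = 1:2, AGE = c(60, 70), SEX = c("M", "F"),
    ETHNICITY = c("not_hispanic", "hispanic"), RACE = c("white", "asian"),
    HANDED = c("right", "left"), EDUCYRS = c(16, 12),
    DXDUR = c(700, 400), SYMPDUR = c(900, 600),
    DOMSIDE = c("left", "right"), GDS = c(5, 6), MOCA = c(27, 25),
    TREMOR = c(1, 0), RIGIDITY = c(1, 1), POSTINST = c(0, 1),
    stringsAsFactors = FALSE)
  X <- encode_features(toy, "all", baseline_total = c(30, 45))
  want <- rbind(c(60, 1, 0, 0, 1, 16, 700, 900, 0, 5, 27, 1, 1, 0, 30),
                c(70, 0, 1, 2, 0, 12, 400, 600, 1, 6, 25, 0, 1, 1, 45))
  expect_equal(unclass(X), want, ignore_attr = TRUE)
  expect_equal(colnames(X)[c(1, 9, 15)],
               c("age", "dominant_side_right", "baseline_updrs"))
  expect_error(encode_features(transform(toy, SEX = c("M", "X")), "all"),
               "unknown value")
})

test_that("feature-set variants drop the columns their names imply", {
  toy <- .toy_cohort(6)
  img <- matrix(rnorm(12), 6, 2, dimnames = list(NULL, c("falff_a", "falff_b")))
  X_all <- encode_features(toy, "all", imaging = img, baseline_total = rnorm(6) + 30)
  expect_true("baseline_updrs" %in% colnames(X_all))
  X_nb <- encode_features(toy, "no_baseline_score", imaging = img,
                          baseline_total = rnorm(6) + 30)
  expect_false("baseline_updrs" %in% colnames(X_nb))
  X_ns <- encode_features(toy, "no_side", imaging = img)
  expect_false("dominant_side_right" %in% colnames(X_ns))
  X_im <- encode_features(toy, "imaging_only", imaging = img)
  expect_true(all(attr(X_im, "provenance") == "imaging"))
  X_cl <- encode_features(toy, "clinical_only", imaging = img)
  expect_false(any(attr(X_cl, "provenance") == "imaging"))
})

test_that("encoding is deterministic across a TSV round-trip", {
  toy <- .toy_cohort(5)
  p <- tempfile(fileext = ".tsv")
  write_cohort(toy, p)
  back <- read_cohort(p)
  X1 <- encode_features(toy, "all")
  X2 <- encode_features(back[, colnames(toy)], "all")
  expect_equal(unclass(X1), unclass(X2), tolerance = 1e-12)
})

test_that("severity threshold averages the four per-time-point medians", {
  th <- severity_threshold(list(c(20, 30, 40), c(35, 35), c(40), c(30, 35, 40)))
  expect_equal(th$value, mean(c(30, 35, 40, 35)))
  same <- severity_threshold(rep(list(c(10, 20, 30, 40)), 4))
  expect_equal(same$value, 25)                        # even-length median rule
  # sort-based oracle on fixed-seed synthetic lists
  set.seed(61)
  lists <- lapply(1:4, function(i) sample(0:80, 15 + i))
  med_oracle <- vapply(lists, function(v) {
    s <- sort(v); n <- length(s)
    if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  }, numeric(1))
  expect_equal(severity_threshold(lists)$value, mean(med_oracle))
  expect_error(severity_threshold(list(1:3, 1:3, numeric(0), 1:3)), "nonempty|one")
})
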