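# a single small study shared by the workflow tests
.wf_study <- local({
  st <- NULL
  function() {
    if (is.null(st)) st <<- synth_study(
      n_baseline = 26, grid_shape = c(10, 10, 10), n_timepoints = 96,
      n_keep_images = 0, seed = 31)
    st
  }
})

test_that("variants imply consistent toggles and reject contradictions", {
  expect_equal(workflow_config("C1")$zscore, FALSE)
  expect_equal(workflow_config("C2")$feature_type, "alff")
  expect_equal(workflow_config("D4")$feature_set, "imaging_only")
  expect_equal(workflow_config("E1")$scheme, "joint")
  expect_error(workflow_config("C1", zscore = TRUE), "contradictory")
  expect_error(workflow_config("Z9"), "unknown variant")
})

test_that("the default report covers every configured family x parcellation", {
  st <- .wf_study()
  rep <- run_workflow(st, workflow_config("default", timepoints = "Baseline",
                                          outer = 5L, inner_k = 4L, seed = 2))
  tab <- rep$metrics
  expect_equal(nrow(tab), 4 * 3)
  expect_setequal(unique(tab$family),
                  c("elasticnet", "linear_svm", "random_forest",
                    "gradient_boosting"))
  expect_setequal(unique(tab$parcellation), c("primary", "coarse", "fine"))
  expect_equal(anyDuplicated(tab[, c("family", "parcellation")]), 0L)
  expect_output(print(rep), "severity threshold")
})

test_that("rerunning a variant with the same seed reproduces the report", {
  st <- .wf_study()
  cfg <- workflow_config("default", families = "elasticnet",
                         parcellations = "primary", timepoints = "Baseline",
                         outer = 5L, inner_k = 4L, seed = 3)
  r1 <- run_workflow(st, cfg)
  r2 <- run_workflow(st, cfg)
  expect_equal(r1$metrics$r2, r2$metrics$r2, tolerance = 1e-12)
  expect_identical(r1$best$Baseline$fit$predictions,
                   r2$best$Baseline$fit$predictions)
})

test_that("C1 differs from default only through the z-scoring stage", {
  st <- .wf_study()
  base_args <- list(families = "elasticnet", parcellations = "primary",
                    timepoints = "Baseline", outer = 5L, inner_k = 4L, seed = 4)
  rd <- run_workflow(st, do.call(workflow_config, c(list("default"), base_args)))
  rc <- run_workflow(st, do.call(workflow_config, c(list("C1"), base_args)))
  # configs agree everywhere except the z-scoring toggle
  cfgd <- rd$config; cfgc <- rc$config
  expect_false(cfgc$zscore); expect_true(cfgd$zscore)
  cfgd$zscore <- cfgc$zscore <- NULL; cfgd$variant <- cfgc$variant <- NULL
  expect_identical(cfgd, cfgc)
  # only the imaging-feature block changes: raw fALFF stays in (0, ~1],
  # z-scored values are centred per participant
  fz <- st$features$falff$primary
  fn <- st$features$falff_nz$primary
  expect_true(all(unclass(fn) > 0 & unclass(fn) < 1.05))
  expect_false(isTRUE(all.equal(unclass(fz), unclass(fn))))
  expect_false(identical(rd$best$Baseline$fit$predictions,
                         rc$best$Baseline$fit$predictions))
})

test_that("D3 (no imaging) importance tables contain no imaging features", {
  st <- .wf_study()
  rep <- run_workflow(st, workflow_config("D3", families = "elasticnet",
                                          parcellations = "primary",
                                          timepoints = "Baseline",
                                          outer = 5L, inner_k = 4L, seed = 5))
  feats <- rep$best$Baseline$fit$importance$feature
  expect_false(any(grepl("^(falff|reho|alff)_", feats)))
})

test_that("comparison flags margin violations and chance-level results", {
  st <- .wf_study()
  cfg <- workflow_config("default", families = "elasticnet",
                         parcellations = "primary", timepoints = "Baseline",
                         outer = 5L, inner_k = 4L, seed = 6)
  rep <- run_workflow(st, cfg)
  cmp <- compare_workflows(list(ref = rep, self = rep))
  expect_true(all(cmp$delta_r2 == 0))
  expect_false(any(cmp$flag_margin))
  # synthetic deltas beyond the margin are flagged
  fake <- rep
  fake$best$Baseline$fit$metrics$r2 <- rep$best$Baseline$fit$metrics$r2 - 0.2
  cmp2 <- compare_workflows(list(ref = rep, worse = fake))
  expect_true(cmp2$flag_margin[cmp2$report == "worse"])
})

test_that("workflow configs round-trip through YAML with validation", {
  p <- tempfile(fileext = ".yaml")
  writeLines(c("variant: D2", "families: [elasticnet]",
               "parcellations: [primary]", "timepoints: [Year1]",
               "inner_k: 4", "seed: 9"), p)
  cfg <- read_workflow_config(p)
  expect_equal(cfg$variant, "D2")
  expect_equal(cfg$feature_set, "no_baseline_score")
  expect_equal(cfg$inner_k, 4)
  writeLines(c("variant: C1", "zscore: yes"), p)
  expect_error(read_workflow_config(p), "contradictory")
  writeLines(c("variant: default", "bogus_field: 1"), p)
  expect_error(read_workflow_config(p), "unknown config field")
})

test_that("reports serialize to JSON + TSV", {
  st <- .wf_study()
  rep <- run_workflow(st, workflow_config("default", families = "elasticnet",
                                          parcellations = "primary",
                                          timepoints = "Baseline",
                                          outer = 5L, inner_k = 4L, seed = 7))
  d <- tempfile()
  write_report(rep, d)
  expect_true(file.exists(file.path(d, "metrics.tsv")))
  js <- jsonlite::read_json(file.path(d, "report.json"))
  expect_equal(js$variant, "default")
  expect_true(is.numeric(js$threshold))
  expect_true(file.exists(file.path(d, "importance_Baseline.tsv")))
})
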