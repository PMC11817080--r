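make_results_row <- function(phecode = "1.1", arm = "indicated", or = 2,
                             p = 0.001, p_adj = 0.001, dropped = FALSE,
                             n_case_with = 20, n_control_with = 50) {
  tibble::tibble(
    phecode = phecode, arm = arm,
    n_case = 400L, n_control = 9000L,
    n_case_with = n_case_with, n_control_with = n_control_with,
    log_or = log(or), se_log_or = 0.2,
    odds_ratio = ifelse(dropped, NA_real_, or),
    ci_low = ifelse(dropped, NA_real_, or * 0.7),
    ci_high = ifelse(dropped, NA_real_, or * 1.5),
    p_value = p, p_adjusted = p_adj,
    separation_flag = dropped, dropped_flag = dropped
  )
}

test_that("Manhattan table computes -log10 adjusted p and status flags", {
  res <- dplyr::bind_rows(
    make_results_row("1.1", p_adj = 0.001),
    make_results_row("2.2", p_adj = 0.2),
    make_results_row("3.3", p_adj = 0.01, dropped = TRUE)
  )
  mt <- manhattan_table(res)
  expect_equal(mt$neg_log10_p_adjusted[mt$phecode == "1.1"], 3)
  expect_equal(mt$status[mt$phecode == "1.1"], "significant")
  expect_equal(mt$status[mt$phecode == "2.2"], "not_significant")
  expect_equal(mt$status[mt$phecode == "3.3"], "dropped")
})

test_that("forest table keeps defined ORs sorted descending", {
  fin <- dplyr::bind_rows(
    make_results_row("1.1", or = 4.25),
    make_results_row("2.2", or = 9.0),
    make_results_row("3.3", dropped = TRUE)
  )
  ft <- forest_table(fin)
  expect_equal(ft$phecode, c("2.2", "1.1"))
  expect_equal(ft$odds_ratio[1], 9.0)
  expect_equal(nrow(forest_table(fin[0, ])), 0)
})

test_that("demographics summarise per group and compare ages with rank tests", {
  u <- dplyr::bind_rows(
    make_units_2x2(5, 5, 0, 40), # 10 indicated, 40 term
    make_units_2x2(0, 0, 0, 0)
  )
  u$delivery_id <- sprintf("D%04d", seq_len(nrow(u)))
  # identical age distributions between indicated and term
  u$maternal_age_years <- rep(c(30, 32, 34, 36, 38), length.out = nrow(u))
  dem <- demographics_table(u)
  expect_true(all(c("categorical", "continuous", "age_comparisons") %in% names(dem)))
  p_ind <- dem$age_comparisons$p_value[
    dem$age_comparisons$comparison == "indicated_vs_term"]
  expect_gt(p_ind, 0.9)
  # spontaneous group is empty: zero counts, comparison skipped
  cat_spo <- dem$categorical[dem$categorical$group == "spontaneous", ]
  expect_true(all(cat_spo$n == 0))
  p_spo <- dem$age_comparisons$p_value[
    dem$age_comparisons$comparison == "spontaneous_vs_term"]
  expect_true(is.na(p_spo))
  # generator-consistency: synthetic mean age near its target
  sim <- simulate_cohort(synthetic_config(n_individuals = 3000, n_phecodes = 10,
                                          seed = 77))
  age <- sim$deliveries$maternal_age_years
  expect_lt(abs(mean(age) - 34.4), 3 * 4.92 / sqrt(length(age)) + 0.2)
})

test_that("small-count redaction masks counts, OR, CI and p-values", {
  tab <- dplyr::bind_rows(
    make_results_row("1.1", n_case_with = 9, n_control_with = 50),
    make_results_row("2.2", n_case_with = 20, n_control_with = 15)
  )
  red <- redact_small_counts(tab, 10)
  expect_true(red$redacted[1])
  expect_false(red$redacted[2])
  expect_true(all(is.na(red[1, c("n_case_with", "odds_ratio", "ci_low",
                                 "ci_high", "p_value", "p_adjusted")])))
  expect_equal(red$odds_ratio[2], 2)
  # threshold 0 is the identity transform
  red0 <- redact_small_counts(tab, 0)
  expect_false(any(red0$redacted))
  expect_equal(red0$odds_ratio, tab$odds_ratio)
})

test_that("the pipeline runs end to end, writes outputs, and is reproducible", {
  out1 <- withr::local_tempdir()
  cfg <- synthetic_config(n_individuals = 700, n_phecodes = 40,
                          planted_effects = headline_effects(), seed = 88)
  acfg <- analysis_config(seed = 88)
  run1 <- quiet(run_pipeline(synthetic = cfg, config = acfg,
                             arms = c("indicated", "spontaneous"),
                             output_dir = out1))
  expect_s3_class(run1, "ptb_phewas_run")
  expected_files <- c("cohort_units.tsv", "exclusion_tally.tsv",
                      "association_results.tsv", "robustness_results.tsv",
                      "final_hits_indicated.tsv", "manhattan_table.tsv",
                      "forest_table.tsv", "demographics_categorical.tsv",
                      "manifest.json")
  expect_true(all(file.exists(file.path(out1, expected_files))))
  manifest <- jsonlite::read_json(file.path(out1, "manifest.json"))
  expect_equal(manifest$stage_counts$analysis_units, nrow(run1$cohort$units))
  expect_true(manifest$synthetic)

  run2 <- quiet(run_pipeline(synthetic = cfg, config = acfg,
                             arms = c("indicated", "spontaneous")))
  expect_equal(run1$results$p_value, run2$results$p_value)
  expect_identical(lapply(run1$finals, function(f) f$phecode),
                   lapply(run2$finals, function(f) f$phecode))
})

test_that("missing input files abort with an error naming the file", {
  expect_error(run_pipeline(deliveries = "nope_deliveries.csv",
                            diagnoses = "nope_diagnoses.csv"),
               "nope_deliveries.csv")
  d <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(make_deliveries(3), d)
  expect_error(run_pipeline(deliveries = d, diagnoses = "nope_diagnoses.csv"),
               "nope_diagnoses.csv")
})

test_that("file-based inputs run through the bundled ICD map", {
  dir <- withr::local_tempdir()
  set.seed(90)
  n <- 400
  del <- make_deliveries(
    n,
    gestational_age_weeks = round(runif(n, 30, 41), 1),
    maternal_age_years = round(runif(n, 20, 45), 1),
    delivery_date = as.Date("2018-01-01") + sample(0:1500, n, TRUE)
  )
  del$ptb_status_label <- ifelse(del$gestational_age_weeks < 37,
                                 sample(c("medically_indicated", "PPROM"), n, TRUE),
                                 "No")
  dx <- tibble::tibble(
    person_id = sample(del$person_id, 900, TRUE),
    code = sample(c("I10", "E11.9", "K21.9", "F32.9", "XXX"), 900, TRUE),
    code_system = "ICD10CM",
    event_date = as.Date("2014-01-01") + sample(0:1200, 900, TRUE)
  )
  fd <- file.path(dir, "deliveries.csv"); readr::write_csv(del, fd)
  fx <- file.path(dir, "diagnoses.csv"); readr::write_csv(dx, fx)
  run <- quiet(run_pipeline(deliveries = fd, diagnoses = fx,
                            arms = "all", config = analysis_config()))
  expect_gt(nrow(run$results), 0)
  expect_true(all(run$results$phecode %in%
                    c("401.1", "250.2", "530.1", "296.2")))
  expect_false(is.null(run$manifest$input_md5))
})

test_that("the unadjusted sensitivity variant fits intercept + presence only", {
  u <- make_units_2x2(15, 60, 30, 700)
  cfg_nocov <- analysis_config(use_covariates = FALSE)
  res <- quiet(run_phewas(u, "indicated", cfg_nocov))
  o <- or_2x2(15, 60, 30, 700)
  expect_equal(res$log_or, o$log_or, tolerance = 1e-6)
})
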