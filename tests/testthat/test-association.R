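test_that("separation is detected exactly when a contingency cell is empty", {
  expect_true(detect_separation(0, 449, 30, 9641))
  expect_false(detect_separation(9, 409, 7, 9664))
  expect_true(detect_separation(1, 0, 1, 1))
  expect_false(detect_separation(1, 1, 1, 1))
  expect_error(detect_separation(-1, 1, 1, 1), "non-negative")
})

test_that("arm construction pools the right case classes against term", {
  u <- dplyr::bind_rows(
    make_units_2x2(5, 0, 0, 0),               # 5 indicated carriers
    make_units_2x2(0, 0, 0, 90)               # 90 term non-carriers
  )
  u$delivery_id <- sprintf("D%04d", seq_len(nrow(u)))
  spo <- make_units_2x2(3, 0, 0, 0)
  spo$outcome <- factor("spontaneous_ptb", levels = levels(u$outcome))
  spo$delivery_id <- sprintf("S%04d", seq_len(nrow(spo)))
  u <- dplyr::bind_rows(u, spo)

  expect_equal(nrow(arm_cohort(u, "indicated")), 95)
  expect_equal(nrow(arm_cohort(u, "spontaneous")), 93)
  expect_equal(nrow(arm_cohort(u, "all")), 98)
  expect_equal(sum(arm_cohort(u, "all")$y), 8)
  expect_error(arm_cohort(u[u$outcome != "term", ], "indicated"), "empty")
})

test_that("unadjusted fit matches the closed-form cross-product odds ratio", {
  cfg <- analysis_config(use_covariates = FALSE)
  u <- make_units_2x2(20, 50, 80, 850)
  at <- arm_cohort(u, "indicated", cfg)
  res <- fit_association(at, "401.1", cfg)
  oracle <- or_2x2(20, 50, 80, 850)
  expect_equal(oracle$or, 4.25) # (20*850)/(50*80)
  expect_equal(res$log_or, oracle$log_or, tolerance = 1e-6)
  expect_equal(res$se_log_or, oracle$se, tolerance = 1e-6)
  expect_equal(res$p_value, oracle$p, tolerance = 1e-6)
  expect_equal(res$n_case_with, 20)
  expect_equal(res$n_control_with, 80)
})

test_that("covariate-adjusted fit agrees with the stats::glm formula interface", {
  set.seed(31)
  u <- make_units_2x2(30, 120, 90, 900)
  u$education_category <- factor(sample(c("gt12", "eq12", "lt12", "unknown"),
                                        nrow(u), TRUE, c(0.7, 0.15, 0.05, 0.1)),
                                 levels = c("gt12", "lt12", "eq12", "unknown"))
  u$insurance_category <- factor(sample(c("private", "non_private"),
                                        nrow(u), TRUE, c(0.9, 0.1)),
                                 levels = c("private", "non_private", "unknown"))
  cfg <- analysis_config()
  at <- arm_cohort(u, "indicated", cfg)
  res <- fit_association(at, "401.1", cfg)

  carrier <- vapply(at$phecodes, function(v) "401.1" %in% v, logical(1))
  ref <- stats::glm(
    at$y ~ carrier + splines::ns(maternal_age_years, df = 4) +
      education_category + insurance_category,
    family = binomial(), data = at,
    control = stats::glm.control(epsilon = 1e-10, maxit = 50)
  )
  s <- summary(ref)$coefficients["carrierTRUE", ]
  expect_equal(res$log_or, unname(s["Estimate"]), tolerance = 1e-6)
  expect_equal(res$se_log_or, unname(s["Std. Error"]), tolerance = 1e-6)
  expect_equal(res$p_value, unname(s["Pr(>|z|)"]), tolerance = 1e-5)
})

test_that("zero-cell and constant exposures are flagged with undefined OR", {
  cfg <- analysis_config(use_covariates = FALSE)
  # carried by 0 cases / 30 controls
  u <- make_units_2x2(0, 50, 30, 500)
  at <- arm_cohort(u, "indicated", cfg)
  res <- fit_association(at, "401.1", cfg)
  expect_true(res$separation_flag)
  expect_true(res$dropped_flag)
  expect_true(is.na(res$odds_ratio))
  expect_equal(res$p_value, 1)

  # carried by every row: no variation
  u2 <- make_units_2x2(50, 0, 500, 0)
  res2 <- fit_association(arm_cohort(u2, "indicated", cfg), "401.1", cfg)
  expect_true(res2$dropped_flag)
  expect_true(is.na(res2$odds_ratio))
})

test_that("phewas results are deterministic and invariant to row order", {
  set.seed(41)
  cfg <- synthetic_config(n_individuals = 500, n_phecodes = 30, seed = 5)
  sim <- simulate_cohort(cfg)
  ev <- quiet(map_events(sim$diagnoses, sim$phecode_map))
  coh <- quiet(build_cohort(sim$deliveries, ev))
  r1 <- quiet(run_phewas(coh$units, "all"))
  shuffled <- coh$units[sample(nrow(coh$units)), ]
  r2 <- quiet(run_phewas(shuffled, "all"))
  expect_equal(r1$phecode, r2$phecode)
  expect_equal(r1$n_case_with, r2$n_case_with)
  expect_equal(r1$log_or, r2$log_or, tolerance = 1e-6)
  # ordering is deterministic by numeric phecode
  expect_false(is.unsorted(as.numeric(r1$phecode)))
})

test_that("missing maternal age excludes the record from regression with a warning", {
  u <- make_units_2x2(20, 60, 40, 700)
  u$maternal_age_years[1] <- NA
  at <- arm_cohort(u, "indicated", analysis_config())
  expect_warning(res <- fit_association(at, "401.1", analysis_config()),
                 "missing maternal age")
  expect_equal(res$n_case_with, 19) # counts reflect the fitted rows
})

test_that("p-values are approximately uniform under the global null", {
  cfg <- synthetic_config(n_individuals = 2000, n_phecodes = 150, seed = 61,
                          prevalence_range = c(0.02, 0.3))
  sim <- simulate_cohort(cfg)
  ev <- quiet(map_events(sim$diagnoses, sim$phecode_map))
  coh <- quiet(build_cohort(sim$deliveries, ev))
  res <- quiet(run_phewas(coh$units, "all"))
  p <- res$p_value[!res$dropped_flag]
  expect_gt(length(p), 80)
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})
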