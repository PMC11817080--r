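test_that("conception date is delivery minus rounded gestational days", {
  expect_equal(conception_date(as.Date("2020-01-01"), 40), as.Date("2019-03-27"))
  expect_equal(conception_date(as.Date("2020-03-01"), 36), as.Date("2019-06-23"))
  # 36.5 weeks -> 256 days (255.5 rounds to even)
  expect_equal(conception_date(as.Date("2020-03-01"), 36.5),
               as.Date("2020-03-01") - round(36.5 * 7))
  expect_error(conception_date(as.Date("2020-01-01"), 0), "positive")
  expect_error(conception_date(as.Date(NA), 40), "non-missing")
})

test_that("outcome classification follows the label/threshold rules", {
  expect_equal(classify_outcome(35, "PPROM"), "spontaneous_ptb")
  expect_equal(classify_outcome(34, "Termination_Iatrogenic"), "indicated_ptb")
  expect_equal(classify_outcome(38, "spontaneous"), "dropped")
  expect_equal(classify_outcome(36, "No"), "unclassified_ptb")
  expect_equal(classify_outcome(37, "No"), "term") # boundary: >= threshold
  expect_error(classify_outcome(35, "maybe"), "unknown PTB status")
})

test_that("covariate preparation categorizes education/insurance with explicit unknowns", {
  d <- make_deliveries(6,
    education_years = c(16, NA, 12, 11, 13, 12),
    private_insurance = c("yes", "no", "unknown", NA, "yes", "no"),
    maternal_age_years = c(30, 40, NA, 25, 33, 38)
  )
  cov <- prepare_covariates(d)
  expect_equal(as.character(cov$education_category),
               c("gt12", "unknown", "eq12", "lt12", "gt12", "eq12"))
  expect_equal(as.character(cov$insurance_category),
               c("private", "non_private", "unknown", "unknown", "private",
                 "non_private"))
  expect_true(is.na(cov$maternal_age_years[3]))
  # unknown is a level, never an NA
  expect_false(anyNA(cov$education_category))
  expect_false(anyNA(cov$insurance_category))
})

test_that("delivery selection excludes in fixed order with a partition tally", {
  d <- dplyr::bind_rows(
    make_deliveries(1, person_id = "P1", delivery_id = "D1"), # kept
    make_deliveries(1, person_id = "P2", delivery_id = "D1"), # duplicate id
    make_deliveries(1, person_id = "P3", delivery_id = "D3", plurality = 2L),
    make_deliveries(1, person_id = "P4", delivery_id = "D4",
                    gestational_age_weeks = NA),
    make_deliveries(1, person_id = "P5", delivery_id = "D5",
                    delivery_date = as.Date(NA)),
    make_deliveries(1, person_id = "P6", delivery_id = "D6") # no diagnoses
  )
  ev <- make_events("P1", "401.1", "2019-05-01") # before P1 conception
  sel <- quiet(select_deliveries(d, ev, analysis_config()))
  tally <- setNames(sel$exclusion_tally$n, sel$exclusion_tally$reason)
  expect_equal(tally[["duplicate_delivery"]], 1)
  expect_equal(tally[["non_singleton"]], 1)
  expect_equal(tally[["missing_ga"]], 1)
  expect_equal(tally[["missing_delivery_date"]], 1)
  expect_equal(tally[["no_prior_diagnosis"]], 1)
  expect_equal(sel$included$delivery_id, "D1")
  # partition: included + excluded == input
  expect_equal(nrow(sel$included) + sum(sel$exclusion_tally$n), nrow(d))

  # sensitivity variant keeps diagnosis-free individuals
  sel2 <- quiet(select_deliveries(d, ev,
                                  analysis_config(require_prior_diagnosis = FALSE)))
  expect_setequal(sel2$included$delivery_id, c("D1", "D6"))
})

test_that("classification truth table is exhaustive over labels x GA", {
  labels <- c("No", "spontaneous", "PPROM", "medically_indicated",
              "Termination_Iatrogenic", "PTL_with_TOCO_and_TERM")
  grid <- expand.grid(ga = c(30, 40), label = labels, stringsAsFactors = FALSE)
  got <- classify_outcome(grid$ga, grid$label)
  expect_true(all(got %in% c("term", "spontaneous_ptb", "indicated_ptb",
                             "unclassified_ptb", "dropped")))
  # every preterm row classifies into a PTB class, every term-age row into
  # term or dropped
  expect_true(all(got[grid$ga < 37] %in%
                    c("spontaneous_ptb", "indicated_ptb", "unclassified_ptb")))
  expect_true(all(got[grid$ga >= 37] %in% c("term", "dropped")))
})

test_that("cohort build drops GA/status mismatches and tallies them", {
  d <- dplyr::bind_rows(
    make_deliveries(1, person_id = "P1", delivery_id = "D1",
                    gestational_age_weeks = 39, ptb_status_label = "No"),
    make_deliveries(1, person_id = "P2", delivery_id = "D2",
                    gestational_age_weeks = 38, ptb_status_label = "spontaneous"),
    make_deliveries(1, person_id = "P3", delivery_id = "D3",
                    gestational_age_weeks = 35, ptb_status_label = "No")
  )
  ev <- make_events(c("P1", "P2", "P3"), "401.1", "2019-01-01")
  coh <- quiet(build_cohort(d, ev, analysis_config()))
  tally <- setNames(coh$exclusion_tally$n, coh$exclusion_tally$reason)
  expect_equal(tally[["ga_label_mismatch"]], 1)
  expect_setequal(coh$units$delivery_id, c("D1", "D3"))
  expect_equal(as.character(coh$units$outcome[coh$units$delivery_id == "D3"]),
               "unclassified_ptb")
})

test_that("no assigned phecode event lies on/after conception or in a postpartum window", {
  cfg <- synthetic_config(n_individuals = 400, n_phecodes = 40, seed = 99)
  sim <- simulate_cohort(cfg)
  ev <- quiet(map_events(sim$diagnoses, sim$phecode_map))
  coh <- quiet(build_cohort(sim$deliveries, ev))
  u <- coh$units
  # rebuild each unit's admissible window and check every assigned phecode
  # has at least one event within it and none outside
  for (i in sample(nrow(u), 50)) {
    prev <- u$delivery_date[u$person_id == u$person_id[i] &
                              u$delivery_date < u$delivery_date[i]]
    start <- if (length(prev) > 0) max(prev) + 183 else as.Date("1900-01-01")
    pev <- ev[ev$person_id == u$person_id[i] &
                ev$event_date < u$conception_date[i] &
                ev$event_date >= start, ]
    expect_setequal(u$phecodes[[i]], unique(pev$phecode))
  }
})

test_that("overlapping pregnancies trigger a warning and empty windows", {
  d <- dplyr::bind_rows(
    make_deliveries(1, person_id = "P1", delivery_id = "D1",
                    delivery_date = as.Date("2019-06-01"),
                    gestational_age_weeks = 39),
    # conception before previous delivery (data error)
    make_deliveries(1, person_id = "P1", delivery_id = "D2",
                    delivery_date = as.Date("2019-12-01"),
                    gestational_age_weeks = 39)
  )
  ev <- make_events("P1", "401.1", "2019-07-01")
  expect_warning(out <- assign_diagnoses(ev, d), "conceive before")
  expect_equal(out[["D2"]], character(0))
})
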