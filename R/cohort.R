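#' Derive the conception date from delivery date and gestational age
#'
#' The start of pregnancy is obtained by subtracting the gestational age from
#' the delivery date, with weeks converted to whole days by rounding
#' (`round(weeks * 7)`).
#'
#' @param delivery_date Date vector (or ISO-8601 strings).
#' @param gestational_age_weeks Positive numeric vector of gestational ages.
#' @return Date vector of conception dates.
#' @export
#' @examples
#' conception_date(as.Date("2020-01-01"), 40) # 2019-03-27
conception_date <- function(delivery_date, gestational_age_weeks) {
  delivery_date <- as.Date(delivery_date)
  if (anyNA(delivery_date) || anyNA(gestational_age_weeks)) {
    stop("conception_date() requires non-missing delivery date and gestational age",
         call. = FALSE)
  }
  if (any(gestational_age_weeks <= 0)) {
    stop("gestational age must be positive", call. = FALSE)
  }
  delivery_date - round(gestational_age_weeks * 7)
}

#' Classify a delivery's outcome from gestational age and curated PTB status
#'
#' Deliveries before the term threshold with an indicated-type label
#' (`medically_indicated`, `Termination_Iatrogenic`) are `indicated_ptb`;
#' those with a spontaneous-type label (`spontaneous`, `PPROM`,
#' `PTL_with_TOCO_and_TERM`) are `spontaneous_ptb`; preterm deliveries
#' labelled `No` are `unclassified_ptb`. At or past the threshold, label `No`
#' gives `term` while any preterm-type label is a gestational-age/status
#' mismatch and the delivery is `dropped`.
#'
#' @param gestational_age_weeks Numeric vector, non-missing.
#' @param label Character vector of curated PTB status labels (see
#'   [analysis_config()] documentation for the accepted values).
#' @param config An [analysis_config()].
#' @return Character vector over
#'   `c("term","spontaneous_ptb","indicated_ptb","unclassified_ptb","dropped")`.
#' @export
classify_outcome <- function(gestational_age_weeks, label,
                             config = analysis_config()) {
  config <- as_ptb_config(config)
  if (anyNA(gestational_age_weeks)) {
    stop("classify_outcome() requires non-missing gestational age", call. = FALSE)
  }
  label <- as.character(label)
  bad <- setdiff(unique(label), ptb_status_levels())
  if (length(bad) > 0) {
    stop("unknown PTB status label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  preterm <- gestational_age_weeks < config$term_threshold_weeks
  indicated <- label %in% c("medically_indicated", "Termination_Iatrogenic")
  spontaneous <- label %in% c("spontaneous", "PPROM", "PTL_with_TOCO_and_TERM")

  out <- character(length(label))
  out[preterm & indicated] <- "indicated_ptb"
  out[preterm & spontaneous] <- "spontaneous_ptb"
  out[preterm & label == "No"] <- "unclassified_ptb"
  out[!preterm & label == "No"] <- "term"
  out[!preterm & label != "No"] <- "dropped"
  out
}

#' Prepare regression covariates from delivery records
#'
#' Maternal education in years is reduced to the categories `lt12` / `eq12` /
#' `gt12`; private-insurance status to `private` / `non_private`. Missing
#' values become the explicit level `unknown` (missingness is modelled as its
#' own category, not dropped). Maternal age is passed through as numeric and
#' may be missing; records missing age are excluded later, at regression
#' time, with a warning.
#'
#' @param deliveries Data frame with columns `maternal_age_years`,
#'   `education_years`, `private_insurance` (values `yes`/`no`/`unknown`/NA).
#' @return Tibble with columns `maternal_age_years`, `education_category`,
#'   `insurance_category` (factors with fixed level sets).
#' @export
prepare_covariates <- function(deliveries) {
  edu <- suppressWarnings(as.numeric(deliveries$education_years))
  education <- dplyr::case_when(
    is.na(edu) ~ "unknown",
    edu < 12 ~ "lt12",
    edu == 12 ~ "eq12",
    TRUE ~ "gt12"
  )
  ins_raw <- tolower(as.character(deliveries$private_insurance))
  insurance <- dplyr::case_when(
    is.na(ins_raw) | ins_raw == "unknown" ~ "unknown",
    ins_raw %in% c("yes", "private", "true", "1") ~ "private",
    ins_raw %in% c("no", "public", "false", "0") ~ "non_private",
    TRUE ~ "unknown"
  )
  tibble::tibble(
    maternal_age_years = suppressWarnings(as.numeric(deliveries$maternal_age_years)),
    # reference levels first: gt12 education and private insurance are the
    # modal categories and serve as the dummy-coding baselines
    education_category = factor(education, levels = c("gt12", "lt12", "eq12", "unknown")),
    insurance_category = factor(insurance, levels = c("private", "non_private", "unknown"))
  )
}

# structural selection steps, applied in a fixed, documented order so the
# exclusion tally is reproducible (each delivery is excluded at the first
# criterion it fails)
select_structural <- function(deliveries) {
  tally <- c(duplicate_delivery = 0L, non_singleton = 0L,
             missing_ga = 0L, missing_delivery_date = 0L)
  d <- tibble::as_tibble(deliveries)

  dup <- duplicated(d$delivery_id)
  tally["duplicate_delivery"] <- sum(dup)
  d <- d[!dup, , drop = FALSE]

  plur <- ifelse(is.na(d$plurality), 1L, d$plurality)
  tally["non_singleton"] <- sum(plur > 1)
  d <- d[plur <= 1, , drop = FALSE]

  no_ga <- is.na(d$gestational_age_weeks)
  tally["missing_ga"] <- sum(no_ga)
  d <- d[!no_ga, , drop = FALSE]

  no_date <- is.na(d$delivery_date)
  tally["missing_delivery_date"] <- sum(no_date)
  d <- d[!no_date, , drop = FALSE]

  list(deliveries = d, tally = tally)
}

#' Apply the cohort selection flow
#'
#' Excludes deliveries in fixed order — duplicate delivery records,
#' non-singleton (plurality > 1), missing gestational age, missing delivery
#' date, and (when `require_prior_diagnosis` is on) pregnancies with no
#' windowed pre-conception diagnosis — tallying each exclusion under a stable
#' reason key. Each delivery is counted against the first criterion it fails.
#'
#' @param deliveries Delivery table (see [load_delivery_table()]).
#' @param phecode_events Mapped phecode events from [map_events()].
#' @param config An [analysis_config()].
#' @return A list with `included` (tibble of retained deliveries) and
#'   `exclusion_tally` (tibble of `reason`, `n` in exclusion order).
#' @export
select_deliveries <- function(deliveries, phecode_events,
                              config = analysis_config()) {
  config <- as_ptb_config(config)
  sel <- select_structural(deliveries)
  d <- sel$deliveries
  tally <- sel$tally

  tally["no_prior_diagnosis"] <- 0L
  if (config$require_prior_diagnosis && nrow(d) > 0) {
    d$conception_date <- conception_date(d$delivery_date, d$gestational_age_weeks)
    exposures <- assign_diagnoses(phecode_events, d, config)
    n_dx <- vapply(exposures[as.character(d$delivery_id)], length, integer(1))
    tally["no_prior_diagnosis"] <- sum(n_dx == 0)
    d <- d[n_dx > 0, , drop = FALSE]
  }

  list(
    included = tibble::as_tibble(d),
    exclusion_tally = tibble::tibble(reason = names(tally), n = unname(tally))
  )
}

# windows for each delivery of each person: [previous delivery + exclusion
# days, conception), or [record start, conception) for the first recorded
# pregnancy (encoded as window_start = NA)
pregnancy_windows <- function(deliveries, config) {
  d <- tibble::as_tibble(deliveries)
  if (!"conception_date" %in% names(d)) {
    d$conception_date <- conception_date(d$delivery_date, d$gestational_age_weeks)
  }
  d <- d |>
    dplyr::arrange(.data$person_id, .data$delivery_date) |>
    dplyr::group_by(.data$person_id) |>
    dplyr::mutate(
      prev_delivery = dplyr::lag(.data$delivery_date),
      window_start = .data$prev_delivery + config$postpartum_exclusion_days
    ) |>
    dplyr::ungroup()

  overlap <- !is.na(d$prev_delivery) & d$conception_date < d$prev_delivery
  if (any(overlap)) {
    warning(sum(overlap), " pregnancy(ies) conceive before the previous ",
            "delivery; their exposure windows are empty", call. = FALSE)
  }
  dplyr::select(d, "person_id", "delivery_id", "window_start",
                window_end = "conception_date")
}

#' Assign pre-conception phecode exposures to pregnancies
#'
#' For each person's first recorded pregnancy the exposure window runs from
#' the start of record to conception; for each subsequent pregnancy it starts
#' `postpartum_exclusion_days` (default 183, i.e. six months) after the
#' previous delivery. Windows are half-open `[start, conception)`: an event on
#' the conception date itself is excluded, an event exactly on day
#' `postpartum_exclusion_days` after the previous delivery is included.
#' Exposure is binary — a phecode is in a pregnancy's set if at least one of
#' its events falls inside the window. Pregnancies whose window is empty
#' (conception before the previous delivery plus the exclusion period) get an
#' empty set, with a data-integrity warning when conception precedes the
#' previous delivery outright.
#'
#' @param phecode_events Tibble from [map_events()].
#' @param deliveries Delivery table for one or more persons, with
#'   `delivery_date` and `gestational_age_weeks` (conception dates are derived
#'   if absent).
#' @param config An [analysis_config()].
#' @return Named list mapping `delivery_id` to a character vector of phecodes.
#' @export
assign_diagnoses <- function(phecode_events, deliveries,
                             config = analysis_config()) {
  config <- as_ptb_config(config)
  windows <- pregnancy_windows(deliveries, config)

  ev <- tibble::as_tibble(phecode_events)
  hits <- dplyr::inner_join(ev, windows, by = "person_id",
                            relationship = "many-to-many") |>
    dplyr::filter(
      .data$event_date < .data$window_end,
      is.na(.data$window_start) | .data$event_date >= .data$window_start
    ) |>
    dplyr::distinct(.data$delivery_id, .data$phecode)

  out <- split(hits$phecode, factor(as.character(hits$delivery_id),
                                    levels = as.character(windows$delivery_id)))
  lapply(out, as.character)
}

#' Build the analysis-ready pregnancy cohort
#'
#' Runs the full preparation flow: structural selection, outcome
#' classification (with gestational-age/status mismatches dropped and
#' tallied), windowed exposure assignment, the prior-diagnosis inclusion
#' criterion, and covariate preparation.
#'
#' @param deliveries Delivery table (see [load_delivery_table()]).
#' @param phecode_events Mapped phecode events from [map_events()].
#' @param config An [analysis_config()].
#' @return A list of class `ptb_cohort` with
#'   * `units`: one row per analysis-ready pregnancy — ids, `outcome`,
#'     `conception_date`, `delivery_date`, `gestational_age_weeks`,
#'     covariates, and a `phecodes` list-column of binary exposures;
#'   * `exclusion_tally`: tibble of exclusion reasons and counts, in order.
#' @export
build_cohort <- function(deliveries, phecode_events,
                         config = analysis_config()) {
  config <- as_ptb_config(config)
  sel <- select_structural(deliveries)
  d <- sel$deliveries
  tally <- sel$tally

  d$outcome <- classify_outcome(d$gestational_age_weeks, d$ptb_status_label, config)
  tally["ga_label_mismatch"] <- sum(d$outcome == "dropped")
  d <- d[d$outcome != "dropped", , drop = FALSE]

  d$conception_date <- conception_date(d$delivery_date, d$gestational_age_weeks)
  exposures <- assign_diagnoses(phecode_events, d, config)
  d$phecodes <- unname(exposures[as.character(d$delivery_id)])

  tally["no_prior_diagnosis"] <- 0L
  if (config$require_prior_diagnosis) {
    n_dx <- lengths(d$phecodes)
    tally["no_prior_diagnosis"] <- sum(n_dx == 0)
    d <- d[n_dx > 0, , drop = FALSE]
  }

  cov <- prepare_covariates(d)
  units <- tibble::tibble(
    delivery_id = d$delivery_id,
    person_id = d$person_id,
    outcome = factor(d$outcome, levels = setdiff(outcome_levels(), "dropped")),
    conception_date = d$conception_date,
    delivery_date = as.Date(d$delivery_date),
    gestational_age_weeks = d$gestational_age_weeks,
    maternal_age_years = cov$maternal_age_years,
    education_category = cov$education_category,
    insurance_category = cov$insurance_category,
    phecodes = d$phecodes
  )
  units$n_phecodes <- lengths(units$phecodes)

  structure(
    list(
      units = units,
      exclusion_tally = tibble::tibble(reason = names(tally), n = unname(tally))
    ),
    class = "ptb_cohort"
  )
}

#' @export
print.ptb_cohort <- function(x, ...) {
  cat("<ptb_cohort> ", nrow(x$units), " pregnancies\n", sep = "")
  print(table(x$units$outcome))
  invisible(x)
}
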