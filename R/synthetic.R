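#' Synthetic EHR generator configuration
#'
#' Describes the study-like conditions the simulator emulates: cohort scale
#' and repeat-pregnancy rate, baseline outcome mix (~9% preterm split roughly
#' evenly between spontaneous and indicated, with a small unclassifiable
#' remainder), a rare-diagnosis prevalence spectrum (log-uniform, most
#' phecodes below 1%), Table-1-style covariate distributions (maternal age
#' approximately normal with mean 34.4 and SD 4.92, truncated to [14, 55];
#' mostly college-educated and privately insured; education missing at 7.9%,
#' insurance at 0.4%), and diagnosis dates falling off exponentially before
#' conception (mean 1.6 years).
#'
#' @param n_individuals Number of synthetic persons.
#' @param pregnancies_per_person Named probability vector over pregnancy
#'   counts (default one pregnancy with probability 0.88, two with 0.12).
#' @param baseline_outcome_probs Named simplex over
#'   `term`/`spontaneous`/`indicated`/`unclassified` at zero linear predictor.
#' @param n_phecodes Size of the phecode universe (planted plus null codes).
#' @param prevalence_range Range of null-phecode per-pregnancy exposure
#'   probabilities. The spectrum is a two-stratum log-uniform: a fraction
#'   `rare_fraction` of phecodes is drawn log-uniformly below `rare_cutoff`
#'   and the rest log-uniformly above it, reproducing the strongly
#'   rare-dominated diagnosis frequency distribution of EHR cohorts.
#' @param rare_fraction Expected fraction of phecodes with prevalence below
#'   `rare_cutoff` (default 0.87).
#' @param rare_cutoff Prevalence cut between the rare and common strata
#'   (default 0.01).
#' @param planted_effects Tibble with columns `phecode`, `prevalence`,
#'   `log_or_indicated`, `log_or_spontaneous` (and optionally `phenotype`);
#'   `NULL` plants nothing (global null).
#' @param age_mean,age_sd,age_range Maternal age model (truncated normal).
#' @param education_probs Named probabilities of `lt12`/`eq12`/`gt12` among
#'   persons with known education.
#' @param p_private Probability of private insurance among persons with known
#'   insurance.
#' @param missingness Named rates: `education`, `insurance`.
#' @param diagnosis_backoff_mean_years Mean of the exponential back-off of
#'   diagnosis dates before conception.
#' @param record_length_mean_years Mean EHR record length before first
#'   conception (exponential, truncated at 21.7 years).
#' @param interpregnancy_gap_days Range (days) of the uniform gap between a
#'   delivery and the next conception; the lower bound must exceed
#'   `postpartum_exclusion_days` so every exposure window is non-empty.
#' @param postpartum_exclusion_days Postpartum window the generator respects
#'   when placing diagnosis dates (matches the analysis default, 183 days).
#' @param covariate_outcome_effects Optional list of named log-odds shifts by
#'   covariate level, e.g.
#'   `list(indicated = c(education_eq12 = 0.3), spontaneous = c())`.
#' @param seed Integer seed; runs with the same seed are byte-identical.
#' @return A list of class `ptb_synth_config`.
#' @export
synthetic_config <- function(n_individuals = 10000,
                             pregnancies_per_person = c(`1` = 0.88, `2` = 0.12),
                             baseline_outcome_probs = c(term = 0.91,
                                                        spontaneous = 0.042,
                                                        indicated = 0.039,
                                                        unclassified = 0.009),
                             n_phecodes = 300,
                             prevalence_range = c(5e-4, 0.08),
                             rare_fraction = 0.87,
                             rare_cutoff = 0.01,
                             planted_effects = NULL,
                             age_mean = 34.4, age_sd = 4.92,
                             age_range = c(14, 55),
                             education_probs = c(lt12 = 0.009, eq12 = 0.147,
                                                 gt12 = 0.765),
                             p_private = 0.936,
                             missingness = c(education = 0.079,
                                             insurance = 0.004),
                             diagnosis_backoff_mean_years = 1.6,
                             record_length_mean_years = 2.0,
                             interpregnancy_gap_days = c(270, 1100),
                             postpartum_exclusion_days = 183L,
                             covariate_outcome_effects = NULL,
                             seed = NULL) {
  if (abs(sum(baseline_outcome_probs) - 1) > 1e-8) {
    stop("baseline_outcome_probs must sum to 1", call. = FALSE)
  }
  stopifnot(
    all(c("term", "spontaneous", "indicated", "unclassified") %in%
          names(baseline_outcome_probs)),
    n_individuals >= 1, n_phecodes >= 1,
    all(prevalence_range > 0), all(prevalence_range < 1),
    interpregnancy_gap_days[1] > postpartum_exclusion_days
  )
  if (!is.null(planted_effects)) {
    planted_effects <- tibble::as_tibble(planted_effects)
    stopifnot(all(c("phecode", "prevalence", "log_or_indicated",
                    "log_or_spontaneous") %in% names(planted_effects)))
  }
  structure(
    list(
      n_individuals = as.integer(n_individuals),
      pregnancies_per_person = pregnancies_per_person,
      baseline_outcome_probs = baseline_outcome_probs,
      n_phecodes = as.integer(n_phecodes),
      prevalence_range = prevalence_range,
      rare_fraction = rare_fraction,
      rare_cutoff = rare_cutoff,
      planted_effects = planted_effects,
      age_mean = age_mean, age_sd = age_sd, age_range = age_range,
      education_probs = education_probs,
      p_private = p_private,
      missingness = missingness,
      diagnosis_backoff_mean_years = diagnosis_backoff_mean_years,
      record_length_mean_years = record_length_mean_years,
      interpregnancy_gap_days = interpregnancy_gap_days,
      postpartum_exclusion_days = as.integer(postpartum_exclusion_days),
      covariate_outcome_effects = covariate_outcome_effects,
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "ptb_synth_config"
  )
}

#' Headline planted effects
#'
#' The preset effect map used for end-to-end evaluation: analogs of essential
#' hypertension (5% prevalence, indicated OR 6, spontaneous OR 1.5), type 1
#' diabetes (1%, indicated OR 11) and type 2 diabetes (2%, indicated OR 6),
#' with no spontaneous effect for the diabetes analogs.
#'
#' @return Tibble of planted effects for [synthetic_config()].
#' @export
headline_effects <- function() {
  tibble::tibble(
    phecode = c("401.1", "250.1", "250.2"),
    phenotype = c("Essential hypertension (synthetic analog)",
                  "Type 1 diabetes (synthetic analog)",
                  "Type 2 diabetes (synthetic analog)"),
    prevalence = c(0.05, 0.01, 0.02),
    log_or_indicated = log(c(6, 11, 6)),
    log_or_spontaneous = log(c(1.5, 1, 1))
  )
}

truncated_normal <- function(n, mean, sd, lower, upper) {
  out <- rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  while (length(bad) > 0) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower | out[bad] > upper]
  }
  out
}

# two-stratum log-uniform prevalence spectrum: most phecodes rare
draw_prevalence <- function(n, lo, hi, rare_fraction, cutoff) {
  if (n == 0) return(numeric(0))
  if (hi <= cutoff || lo >= cutoff) {
    return(exp(runif(n, log(lo), log(hi))))
  }
  rare <- runif(n) < rare_fraction
  low <- exp(runif(n, log(lo), log(cutoff)))
  high <- exp(runif(n, log(cutoff), log(hi)))
  ifelse(rare, low, high)
}

# inverse-CDF draw from an exponential (mean mu) truncated to (0, L], in days
truncated_exp_days <- function(n, mu, L) {
  u <- runif(n)
  d <- -mu * log(1 - u * (1 - exp(-L / mu)))
  pmin(pmax(ceiling(d), 1), L)
}

synth_categories <- function() {
  c("circulatory system", "endocrine/metabolic", "genitourinary",
    "digestive", "respiratory", "hematopoietic", "infectious diseases",
    "mental disorders", "musculoskeletal", "neurological", "dermatologic",
    "sense organs", "injuries & poisonings", "congenital anomalies",
    "symptoms", "neoplasms", "pregnancy complications", "other")
}

#' Simulate a synthetic EHR cohort
#'
#' Generates persons, deliveries and dated diagnosis events with the
#' statistical structure the association pipeline assumes, plus the ground
#' truth needed for recovery evaluation. Per pregnancy, phecode exposures are
#' drawn Bernoulli from the prevalence spectrum; the outcome comes from a
#' four-class multinomial logit (term reference) whose spontaneous- and
#' indicated-class linear predictors add the planted per-arm log odds ratios
#' of carried phecodes (so the arm-restricted logistic model is correctly
#' specified and its conditional OR equals the planted value). Gestational
#' age is drawn uniform 37-41 weeks for term and 24-36.9 for preterm
#' classes; curated status labels are emitted consistently with the outcome
#' (unclassified preterm carries label "No"). Diagnosis dates fall off
#' exponentially before each conception and always respect the exposure
#' window the analysis will apply (record start for a first pregnancy; 183
#' days after the previous delivery otherwise), so windowing recovers the
#' generated exposure sets exactly.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `ptb_synth` with `deliveries`, `diagnoses`,
#'   `phecode_map` (identity map over the synthetic universe, with phenotype
#'   and category annotations), `truth` (per-phecode planted log-ORs and
#'   realized prevalence) and the `config` used.
#' @export
simulate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "ptb_synth_config"))
  with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  n_person <- cfg$n_individuals

  # --- persons -------------------------------------------------------------
  person_id <- sprintf("P%06d", seq_len(n_person))
  n_pregs <- sample(as.integer(names(cfg$pregnancies_per_person)), n_person,
                    replace = TRUE, prob = cfg$pregnancies_per_person)
  base_age <- truncated_normal(n_person, cfg$age_mean, cfg$age_sd,
                               cfg$age_range[1], cfg$age_range[2])
  edu_cat <- sample(names(cfg$education_probs), n_person, replace = TRUE,
                    prob = cfg$education_probs)
  education_years <- ifelse(edu_cat == "lt12", sample(6:11, n_person, TRUE),
                            ifelse(edu_cat == "eq12", 12L,
                                   sample(13:20, n_person, TRUE)))
  education_years[runif(n_person) < cfg$missingness[["education"]]] <- NA
  insurance <- ifelse(runif(n_person) < cfg$p_private, "yes", "no")
  insurance[runif(n_person) < cfg$missingness[["insurance"]]] <- "unknown"

  # --- pregnancies ---------------------------------------------------------
  pidx <- rep.int(seq_len(n_person), n_pregs)
  preg_no <- unlist(lapply(n_pregs, seq_len), use.names = FALSE)
  n_preg <- length(pidx)
  gap_days <- round(runif(n_preg, cfg$interpregnancy_gap_days[1],
                          cfg$interpregnancy_gap_days[2]))

  # --- phecode universe and exposures --------------------------------------
  planted <- cfg$planted_effects
  n_planted <- if (is.null(planted)) 0L else nrow(planted)
  n_null <- cfg$n_phecodes - n_planted
  if (n_null < 0) stop("more planted effects than n_phecodes", call. = FALSE)
  null_codes <- sprintf("%.1f", seq(100.0, by = 0.1, length.out = max(n_null, 0)))
  if (n_planted > 0) null_codes <- setdiff(null_codes, planted$phecode)[seq_len(n_null)]
  universe <- c(if (n_planted > 0) planted$phecode, null_codes)
  prevalence <- c(
    if (n_planted > 0) planted$prevalence,
    draw_prevalence(n_null, cfg$prevalence_range[1], cfg$prevalence_range[2],
                    cfg$rare_fraction, cfg$rare_cutoff)
  )
  beta_ind <- c(if (n_planted > 0) planted$log_or_indicated, rep(0, n_null))
  beta_spo <- c(if (n_planted > 0) planted$log_or_spontaneous, rep(0, n_null))

  carriers <- lapply(seq_along(universe), function(j) {
    which(runif(n_preg) < prevalence[j])
  })
  realized_prev <- lengths(carriers) / n_preg

  # --- outcomes: 4-class multinomial logit, term as reference --------------
  p0 <- cfg$baseline_outcome_probs
  eta_spo <- rep(log(p0[["spontaneous"]] / p0[["term"]]), n_preg)
  eta_ind <- rep(log(p0[["indicated"]] / p0[["term"]]), n_preg)
  eta_unc <- rep(log(p0[["unclassified"]] / p0[["term"]]), n_preg)
  for (j in seq_along(universe)) {
    if (beta_spo[j] != 0) eta_spo[carriers[[j]]] <- eta_spo[carriers[[j]]] + beta_spo[j]
    if (beta_ind[j] != 0) eta_ind[carriers[[j]]] <- eta_ind[carriers[[j]]] + beta_ind[j]
  }
  eff <- cfg$covariate_outcome_effects
  if (!is.null(eff)) {
    level_key <- cbind(
      paste0("education_", ifelse(is.na(education_years[pidx]), "unknown",
                                  ifelse(education_years[pidx] < 12, "lt12",
                                         ifelse(education_years[pidx] == 12, "eq12", "gt12")))),
      paste0("insurance_", ifelse(insurance[pidx] == "yes", "private",
                                  ifelse(insurance[pidx] == "no", "non_private", "unknown")))
    )
    add_shift <- function(eta, shifts) {
      if (is.null(shifts) || length(shifts) == 0) return(eta)
      for (nm in names(shifts)) {
        eta <- eta + shifts[[nm]] * rowSums(level_key == nm)
      }
      eta
    }
    eta_spo <- add_shift(eta_spo, eff$spontaneous)
    eta_ind <- add_shift(eta_ind, eff$indicated)
  }

  expo <- cbind(0, eta_spo, eta_ind, eta_unc)
  pm <- exp(expo - apply(expo, 1, max))
  pm <- pm / rowSums(pm)
  u <- runif(n_preg)
  cum <- t(apply(pm, 1, cumsum))
  outcome_idx <- 1L + rowSums(u > cum)  # 1 term, 2 spont, 3 indicated, 4 uncl
  outcome <- c("term", "spontaneous", "indicated", "unclassified")[outcome_idx]

  ga <- ifelse(outcome == "term", runif(n_preg, 37, 41), runif(n_preg, 24, 36.9))
  ga <- round(ga, 1)
  label <- character(n_preg)
  label[outcome %in% c("term", "unclassified")] <- "No"
  is_spo <- outcome == "spontaneous"
  label[is_spo] <- sample(c("spontaneous", "PPROM", "PTL_with_TOCO_and_TERM"),
                          sum(is_spo), replace = TRUE, prob = c(0.5, 0.3, 0.2))
  is_ind <- outcome == "indicated"
  label[is_ind] <- sample(c("medically_indicated", "Termination_Iatrogenic"),
                          sum(is_ind), replace = TRUE, prob = c(0.7, 0.3))

  # --- dates ---------------------------------------------------------------
  first_conception <- as.Date("2002-01-01") +
    sample.int(6573L, n_person, replace = TRUE) - 1L
  conception <- delivery <- rep(as.Date(NA), n_preg)
  first <- preg_no == 1L
  conception[first] <- first_conception[pidx[first]]
  delivery[first] <- conception[first] + round(ga[first] * 7)
  second <- preg_no == 2L
  if (any(second)) {
    prev_delivery <- delivery[match(pidx[second], pidx)]  # first preg row per person
    conception[second] <- prev_delivery + gap_days[second]
    delivery[second] <- conception[second] + round(ga[second] * 7)
  }
  record_len <- pmin(pmax(round(rexp(n_person,
                                     1 / (cfg$record_length_mean_years * 365.25))),
                          30), 7925)
  window_start <- rep(as.Date(NA), n_preg)
  window_start[first] <- conception[first] - record_len[pidx[first]]
  if (any(second)) {
    window_start[second] <- delivery[match(pidx[second], pidx)] +
      cfg$postpartum_exclusion_days
  }
  window_len <- as.integer(conception - window_start)

  # --- diagnosis events ----------------------------------------------------
  ev_preg <- rep.int(seq_len(n_preg), 0L)
  ev_code <- character(0)
  if (length(universe) > 0) {
    ev_preg <- unlist(carriers, use.names = FALSE)
    ev_code <- rep(universe, lengths(carriers))
  }
  mu <- cfg$diagnosis_backoff_mean_years * 365.25
  d <- truncated_exp_days(length(ev_preg), mu, window_len[ev_preg])
  diagnoses <- tibble::tibble(
    person_id = person_id[pidx[ev_preg]],
    code = ev_code,
    code_system = "PHECODE",
    event_date = conception[ev_preg] - d
  ) |>
    dplyr::arrange(.data$person_id, .data$code, .data$event_date)

  deliveries <- tibble::tibble(
    person_id = person_id[pidx],
    delivery_id = sprintf("D%06d", seq_len(n_preg)),
    delivery_date = delivery,
    gestational_age_weeks = ga,
    plurality = 1L,
    ptb_status_label = label,
    maternal_age_years = round(base_age[pidx] + (preg_no - 1L) * gap_days / 365.25, 1),
    education_years = education_years[pidx],
    private_insurance = insurance[pidx],
    race_label = "synthetic"
  )

  cats <- synth_categories()
  phecode_map <- tibble::tibble(
    code = universe,
    code_system = "PHECODE",
    phecode = universe,
    phenotype = if (n_planted > 0 && "phenotype" %in% names(planted)) {
      c(planted$phenotype, paste("Synthetic phenotype", null_codes))
    } else {
      paste("Synthetic phenotype", universe)
    },
    category = cats[(seq_along(universe) - 1L) %% length(cats) + 1L]
  )

  truth <- tibble::tibble(
    phecode = universe,
    log_or_indicated = beta_ind,
    log_or_spontaneous = beta_spo,
    prevalence_target = prevalence,
    prevalence_realized = realized_prev
  )

  structure(
    list(deliveries = deliveries, diagnoses = diagnoses,
         phecode_map = phecode_map, truth = truth, config = cfg),
    class = "ptb_synth"
  )
}

#' Score pipeline output against the simulator's planted truth
#'
#' For each stratified arm, computes the detection sensitivity on planted
#' (non-zero) effects, the count of null phecodes reaching the final
#' significant-and-robust table (false discoveries), and the fraction of
#' planted phecodes whose 95% CI in the full association results covers the
#' true odds ratio.
#'
#' @param pipeline A [run_pipeline()] result (needs `results` and `finals`).
#' @param truth Truth table from [simulate_cohort()].
#' @return Tibble with one row per arm: `arm`, `n_planted`, `n_detected`,
#'   `sensitivity`, `n_false_discoveries`, `ci_coverage`.
#' @export
evaluate_recovery <- function(pipeline, truth) {
  results <- pipeline$results
  arms <- intersect(c("indicated", "spontaneous"), unique(results$arm))
  purrr::map(arms, function(arm) {
    beta <- if (arm == "indicated") truth$log_or_indicated else truth$log_or_spontaneous
    planted <- truth$phecode[beta != 0]
    arm_res <- results[results$arm == arm, , drop = FALSE]
    observed <- planted[truth$prevalence_realized[beta != 0] > 0]
    if (length(setdiff(observed, arm_res$phecode)) > 0) {
      stop("planted phecode(s) absent from arm '", arm, "' results: ",
           paste(setdiff(observed, arm_res$phecode), collapse = ", "),
           call. = FALSE)
    }
    final <- pipeline$finals[[arm]]
    detected <- intersect(planted, final$phecode)
    nulls_hit <- setdiff(final$phecode, planted)

    cov <- NA_real_
    if (length(planted) > 0) {
      rows <- arm_res[match(planted, arm_res$phecode), , drop = FALSE]
      true_or <- exp(beta[match(planted, truth$phecode)])
      inside <- !is.na(rows$ci_low) & rows$ci_low <= true_or &
        true_or <= rows$ci_high
      cov <- mean(inside)
    }
    tibble::tibble(
      arm = arm,
      n_planted = length(planted),
      n_detected = length(detected),
      sensitivity = if (length(planted) > 0) length(detected) / length(planted) else NA_real_,
      n_false_discoveries = length(nulls_hit),
      ci_coverage = cov
    )
  }) |>
    dplyr::bind_rows()
}
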