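# shared fixture builders; everything is generated in code, no stored data

# minimal delivery row(s) with sensible defaults
make_deliveries <- function(n = 1, person_id = sprintf("P%03d", seq_len(n)),
                            delivery_id = sprintf("D%03d", seq_len(n)),
                            delivery_date = as.Date("2020-06-01"),
                            gestational_age_weeks = 39,
                            plurality = 1L,
                            ptb_status_label = "No",
                            maternal_age_years = 33,
                            education_years = 16,
                            private_insurance = "yes") {
  tibble::tibble(
    person_id = person_id, delivery_id = delivery_id,
    delivery_date = as.Date(delivery_date),
    gestational_age_weeks = gestational_age_weeks,
    plurality = plurality, ptb_status_label = ptb_status_label,
    maternal_age_years = maternal_age_years,
    education_years = education_years,
    private_insurance = private_insurance
  )
}

make_events <- function(person_id, phecode, event_date) {
  tibble::tibble(person_id = person_id, phecode = as.character(phecode),
                 event_date = as.Date(event_date))
}

# analysis-ready units for association-layer tests, built directly:
# a term/indicated cohort with one phecode carried by the given cell counts
make_units_2x2 <- function(n_case_with, n_case_without,
                           n_control_with, n_control_without,
                           phecode = "401.1", seed = 1) {
  n <- n_case_with + n_case_without + n_control_with + n_control_without
  outcome <- c(rep("indicated_ptb", n_case_with + n_case_without),
               rep("term", n_control_with + n_control_without))
  carrier <- c(rep(TRUE, n_case_with), rep(FALSE, n_case_without),
               rep(TRUE, n_control_with), rep(FALSE, n_control_without))
  withr_seed <- function(code) { # local RNG so fixtures don't disturb tests
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed); code
  }
  ages <- withr_seed(round(runif(n, 20, 45), 1))
  tibble::tibble(
    delivery_id = sprintf("D%05d", seq_len(n)),
    person_id = sprintf("P%05d", seq_len(n)),
    outcome = factor(outcome,
                     levels = c("term", "spontaneous_ptb", "indicated_ptb",
                                "unclassified_ptb")),
    conception_date = as.Date("2019-01-01"),
    delivery_date = as.Date("2019-10-01"),
    gestational_age_weeks = ifelse(outcome == "term", 39, 34),
    maternal_age_years = ages,
    education_category = factor("gt12", levels = c("gt12", "lt12", "eq12", "unknown")),
    insurance_category = factor("private", levels = c("private", "non_private", "unknown")),
    phecodes = lapply(carrier, function(cc) if (cc) phecode else character(0)),
    n_phecodes = as.integer(carrier)
  )
}

# independent closed-form 2x2 oracle: cross-product odds ratio and Wald test
or_2x2 <- function(a, b, c, d) {
  log_or <- log((a * d) / (b * c))
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(or = exp(log_or), log_or = log_or, se = se,
       p = 2 * stats::pnorm(-abs(log_or / se)))
}

# independent brute-force BH step-up from the definition:
# adj_(i) = min_{j >= i} min(1, p_(j) * m / j), mapped back to input order
bh_brute <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  idx <- order(p)
  ps <- p[idx]
  adj_sorted <- vapply(seq_len(m), function(i) {
    min(1, min(ps[i:m] * m / (i:m)))
  }, numeric(1))
  adj <- numeric(m)
  adj[idx] <- adj_sorted
  adj
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))
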