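#' Detect complete separation from the exposure-outcome contingency table
#'
#' A phecode's 2x2 table against the binary outcome has a zero cell exactly
#' when the maximum-likelihood odds ratio is undefined (infinite or zero), so
#' separation is flagged whenever any of the four cells is empty.
#'
#' @param n_case_with,n_case_without,n_control_with,n_control_without
#'   Non-negative cell counts.
#' @return Logical: `TRUE` if any cell is zero.
#' @export
#' @examples
#' detect_separation(0, 449, 30, 9641) # TRUE: no exposed cases
detect_separation <- function(n_case_with, n_case_without,
                              n_control_with, n_control_without) {
  counts <- c(n_case_with, n_case_without, n_control_with, n_control_without)
  if (any(counts < 0)) stop("cell counts must be non-negative", call. = FALSE)
  n_case_with == 0 | n_case_without == 0 |
    n_control_with == 0 | n_control_without == 0
}

#' Build one analysis arm's case/control table
#'
#' Cases are the arm's preterm class — `indicated`, `spontaneous`, or `all`
#' (spontaneous + indicated, plus unclassified preterm deliveries when
#' `include_unclassified_in_all_ptb` is on) — and controls are term
#' deliveries. Other pregnancies are excluded from the arm.
#'
#' @param units Cohort units from [build_cohort()].
#' @param arm One of `"indicated"`, `"spontaneous"`, `"all"` (the
#'   `"*_vs_term"` spellings are also accepted).
#' @param config An [analysis_config()].
#' @return The unit tibble restricted to the arm, with a binary `y` column
#'   (1 = case).
#' @export
arm_cohort <- function(units, arm, config = analysis_config()) {
  config <- as_ptb_config(config)
  arm <- normalize_arm(arm)
  units <- if (inherits(units, "ptb_cohort")) units$units else units

  case_classes <- switch(
    arm,
    indicated = "indicated_ptb",
    spontaneous = "spontaneous_ptb",
    all = c("spontaneous_ptb", "indicated_ptb",
            if (config$include_unclassified_in_all_ptb) "unclassified_ptb")
  )
  keep <- units$outcome %in% c(case_classes, "term")
  at <- units[keep, , drop = FALSE]
  at$y <- as.integer(at$outcome %in% case_classes)
  if (sum(at$y) == 0 || sum(at$y == 0) == 0) {
    stop("arm '", arm, "' has an empty case or control group", call. = FALSE)
  }
  attr(at, "arm") <- arm
  at
}

# deterministic phecode ordering: numeric value, ties broken lexically
sort_phecodes <- function(ph) {
  ph <- unique(as.character(ph))
  ph[order(suppressWarnings(as.numeric(ph)), ph)]
}

# units x phecodes logical exposure matrix from the list-column
exposure_matrix <- function(phecode_sets, phecodes) {
  n <- length(phecode_sets)
  m <- matrix(FALSE, n, length(phecodes), dimnames = list(NULL, phecodes))
  idx <- unlist(phecode_sets, use.names = FALSE)
  if (length(idx) > 0) {
    i <- rep.int(seq_len(n), lengths(phecode_sets))
    j <- match(idx, phecodes)
    ok <- !is.na(j)
    m[cbind(i[ok], j[ok])] <- TRUE
  }
  m
}

# natural-cubic-spline age basis plus dummy-coded education and insurance.
# Levels absent from the arm are dropped so the design stays full rank.
covariate_matrix <- function(at, config) {
  age_basis <- splines::ns(at$maternal_age_years, df = config$spline_df)
  colnames(age_basis) <- paste0("age_ns", seq_len(ncol(age_basis)))
  edu <- droplevels(at$education_category)
  ins <- droplevels(at$insurance_category)
  parts <- list(age_basis)
  if (nlevels(edu) > 1) {
    m <- stats::model.matrix(~edu)[, -1, drop = FALSE]
    colnames(m) <- sub("^edu", "education_", colnames(m))
    parts <- c(parts, list(m))
  }
  if (nlevels(ins) > 1) {
    m <- stats::model.matrix(~ins)[, -1, drop = FALSE]
    colnames(m) <- sub("^ins", "insurance_", colnames(m))
    parts <- c(parts, list(m))
  }
  do.call(cbind, parts)
}

# IRLS logistic fit via stats::glm.fit with summary.glm-style SE extraction
logit_fit <- function(X, y, start = NULL) {
  fit <- tryCatch(
    suppressWarnings(glm.fit(X, y, family = binomial(), start = start,
                             control = stats::glm.control(epsilon = 1e-10,
                                                          maxit = 50))),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(list(coef = rep(NA_real_, ncol(X)), se = rep(NA_real_, ncol(X)),
                converged = FALSE))
  }
  coefs <- fit$coefficients
  se <- rep(NA_real_, length(coefs))
  r <- fit$rank
  if (r > 0) {
    Qr <- fit$qr
    cov_unscaled <- chol2inv(Qr$qr[seq_len(r), seq_len(r), drop = FALSE])
    se[Qr$pivot[seq_len(r)]] <- sqrt(diag(cov_unscaled))
  }
  list(coef = coefs, se = se, converged = isTRUE(fit$converged))
}

# one phecode's association given the design pieces; `start` warm-starts the
# IRLS from the covariate-only fit
fit_one_phecode <- function(phecode, arm, carrier, y, covmat, start = NULL) {
  n_case_with <- sum(carrier & y == 1L)
  n_control_with <- sum(carrier & y == 0L)
  n_case <- sum(y == 1L)
  n_control <- sum(y == 0L)
  separated <- detect_separation(n_case_with, n_case - n_case_with,
                                 n_control_with, n_control - n_control_with)

  if (separated) {
    # the ML odds ratio is undefined and the Wald statistic degenerate
    # (Hauck-Donner), so no model is fitted; the conventional p of 1 keeps
    # the phecode in the BH vector (m = all tested phecodes) while the
    # dropped flag bars it from significance candidacy
    beta <- se <- NA_real_
    p <- 1
    dropped <- TRUE
  } else {
    X <- cbind(`(Intercept)` = 1, carrier = as.numeric(carrier), covmat)
    f <- logit_fit(X, y, start = start)
    unstable <- function(ft) {
      is.na(ft$coef[2]) || is.na(ft$se[2]) || !ft$converged ||
        abs(ft$coef[2]) > 15 || ft$se[2] > 1e3
    }
    # a warm start occasionally sends IRLS down a degenerate path even for
    # well-behaved tables; retry cold before declaring the fit unstable
    if (!is.null(start) && unstable(f)) {
      f <- logit_fit(X, y, start = NULL)
    }
    beta <- unname(f$coef[2])
    se <- unname(f$se[2])
    z <- beta / se
    # clamp at the smallest positive double: extreme Wald z underflows to 0,
    # and downstream BH machinery requires p in (0, 1]
    p <- max(2 * pnorm(-abs(z)), .Machine$double.xmin)

    # quasi-separation and non-convergence share the undefined/flagged pathway;
    # their Wald statistics are numerically meaningless, so they contribute
    # p = 1 to the BH vector rather than a garbage value that could outrank
    # valid tests
    dropped <- is.na(beta) || is.na(se) || !f$converged ||
      abs(beta) > 15 || se > 1e3
    if (dropped) {
      beta <- se <- NA_real_
      p <- 1
    }
  }

  tibble::tibble(
    phecode = phecode,
    arm = arm,
    n_case = n_case,
    n_control = n_control,
    n_case_with = n_case_with,
    n_control_with = n_control_with,
    log_or = if (dropped) NA_real_ else beta,
    se_log_or = if (dropped) NA_real_ else se,
    odds_ratio = if (dropped) NA_real_ else exp(beta),
    ci_low = if (dropped) NA_real_ else exp(beta - 1.96 * se),
    ci_high = if (dropped) NA_real_ else exp(beta + 1.96 * se),
    p_value = if (is.na(p)) NA_real_ else p,
    p_adjusted = NA_real_,
    separation_flag = separated,
    dropped_flag = dropped
  )
}

#' Fit one phecode's covariate-adjusted association
#'
#' Logistic regression of the arm outcome on binary phecode presence plus —
#' unless `use_covariates` is off — the maternal-age spline basis and the
#' education/insurance dummies. The odds ratio is `exp` of the presence
#' coefficient with a 95% Wald interval (`exp(beta +/- 1.96 se)`) and a
#' two-sided Wald p-value. Complete separation (a zero cell in the 2x2
#' exposure/outcome table), quasi-separation and non-convergence are flagged
#' rather than raised: the OR and CI are reported as undefined (`NA`) and the
#' result is excluded from significance candidacy downstream.
#'
#' @param arm_table Output of [arm_cohort()].
#' @param phecode Single phecode string with at least one carrier in the arm.
#' @param config An [analysis_config()].
#' @return One-row tibble (see [run_phewas()] for the column set).
#' @export
fit_association <- function(arm_table, phecode, config = analysis_config()) {
  config <- as_ptb_config(config)
  at <- arm_table
  carrier <- vapply(at$phecodes, function(v) phecode %in% v, logical(1))
  if (sum(carrier) == 0) {
    stop("phecode ", phecode, " has no carriers in this arm", call. = FALSE)
  }
  covmat <- NULL
  if (config$use_covariates) {
    drop_age <- is.na(at$maternal_age_years)
    if (any(drop_age)) {
      warning(sum(drop_age), " record(s) missing maternal age excluded from ",
              "regression", call. = FALSE)
      at <- at[!drop_age, , drop = FALSE]
      carrier <- carrier[!drop_age]
    }
    covmat <- covariate_matrix(at, config)
  }
  arm_label <- attr(arm_table, "arm") %||% "arm"
  fit_one_phecode(phecode, arm_label, carrier, at$y, covmat)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the per-phecode association scan for one arm
#'
#' Tests every phecode carried by at least one pregnancy in the arm with a
#' covariate-adjusted logistic regression ([fit_association()] semantics),
#' returning one row per phecode in deterministic (numeric phecode) order.
#' Each fit is warm-started from the covariate-only model for speed; results
#' are identical to cold fits up to IRLS convergence tolerance.
#'
#' @param units Cohort units (or a `ptb_cohort`).
#' @param arm Arm name (see [arm_cohort()]).
#' @param config An [analysis_config()].
#' @return Tibble with columns `phecode`, `arm`, `n_case`, `n_control`,
#'   `n_case_with`, `n_control_with`, `log_or`, `se_log_or`, `odds_ratio`,
#'   `ci_low`, `ci_high`, `p_value`, `p_adjusted` (filled by
#'   [adjust_results()]), `separation_flag`, `dropped_flag`.
#' @export
run_phewas <- function(units, arm, config = analysis_config()) {
  config <- as_ptb_config(config)
  arm <- normalize_arm(arm)
  at <- arm_cohort(units, arm, config)

  covmat <- NULL
  start <- NULL
  if (config$use_covariates) {
    drop_age <- is.na(at$maternal_age_years)
    if (any(drop_age)) {
      warning(sum(drop_age), " record(s) missing maternal age excluded from ",
              "regression", call. = FALSE)
      at <- at[!drop_age, , drop = FALSE]
    }
    covmat <- covariate_matrix(at, config)
    base <- logit_fit(cbind(1, covmat), at$y)
    if (base$converged && !anyNA(base$coef)) {
      start <- c(base$coef[1], 0, base$coef[-1])
    }
  } else {
    base_rate <- mean(at$y)
    start <- c(log(base_rate / (1 - base_rate)), 0)
  }

  phecodes <- sort_phecodes(unlist(at$phecodes, use.names = FALSE))
  expo <- exposure_matrix(at$phecodes, phecodes)
  y <- at$y

  results <- purrr::map(phecodes, function(ph) {
    fit_one_phecode(ph, arm, expo[, ph], y, covmat, start = start)
  })
  out <- dplyr::bind_rows(results)
  message("arm '", arm, "': tested ", nrow(out), " phecodes (",
          sum(out$dropped_flag), " flagged undefined/unstable)")
  out
}
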