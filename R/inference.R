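#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH adjusted p-values, order-preserving with the input, clipped at
#' 1, with `m` equal to the number of supplied p-values (i.e. the number of
#' tested phecodes in an arm). Thin validated wrapper around
#' [stats::p.adjust()].
#'
#' @param p_values Numeric vector of raw p-values in (0, 1].
#' @return Numeric vector of adjusted p-values, same order as input.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (anyNA(p_values) || any(p_values <= 0 | p_values > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  p.adjust(p_values, method = "BH")
}

#' Fill BH-adjusted p-values into a result table
#'
#' Adjusts within each arm, with `m` = number of phecodes carrying a defined
#' raw p-value in that arm (results whose fit produced no p-value stay `NA`).
#'
#' @param results Association results from [run_phewas()] (one or several
#'   arms bound together).
#' @return The same tibble with `p_adjusted` filled.
#' @export
adjust_results <- function(results) {
  results |>
    dplyr::group_by(.data$arm) |>
    dplyr::mutate(p_adjusted = {
      adj <- rep(NA_real_, dplyr::n())
      ok <- !is.na(.data$p_value)
      adj[ok] <- bh_adjust(.data$p_value[ok])
      adj
    }) |>
    dplyr::ungroup()
}

#' Select significant associations
#'
#' Keeps results with `p_adjusted` strictly below the FDR threshold and a
#' defined odds ratio. Significant results whose odds ratio is undefined
#' (separated/unstable fits) are dropped from candidacy and reported via
#' `message()` and the `dropped_undefined` attribute.
#'
#' @param results Adjusted results from [adjust_results()].
#' @param config An [analysis_config()].
#' @return Tibble of selected results; dropped undefined-OR hits in the
#'   `dropped_undefined` attribute.
#' @export
select_significant <- function(results, config = analysis_config()) {
  config <- as_ptb_config(config)
  if (all(is.na(results$p_adjusted)) && nrow(results) > 0 &&
      any(!is.na(results$p_value))) {
    stop("p_adjusted has not been filled; call adjust_results() first",
         call. = FALSE)
  }
  sig <- !is.na(results$p_adjusted) & results$p_adjusted < config$fdr_alpha
  dropped <- results[sig & results$dropped_flag, , drop = FALSE]
  if (nrow(dropped) > 0) {
    message(nrow(dropped), " significant association(s) with undefined odds ",
            "ratios dropped: ", paste(dropped$phecode, collapse = ", "))
  }
  out <- results[sig & !results$dropped_flag, , drop = FALSE]
  attr(out, "dropped_undefined") <- dropped
  out
}

# evaluate `code` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Leave-one-carrier-out stability test for one significant phecode
#'
#' Re-tests an association repeatedly, each iteration removing a single
#' carrier pregnancy (case or control) from the arm and refitting that
#' phecode's model. If the phecode has fewer carriers than
#' `robustness_iterations` (default 50), every carrier is removed in exactly
#' one iteration; otherwise `robustness_iterations` distinct carriers are
#' drawn uniformly without replacement under `seed`. Within each iteration
#' the phecode's raw p-value is replaced in the arm's full p-vector and BH is
#' recomputed; the iteration counts as significant iff the adjusted p-value
#' stays below `fdr_alpha` with a defined odds ratio. The association is
#' robust iff every iteration is significant.
#'
#' @param units Cohort units (or a `ptb_cohort`).
#' @param arm Arm name.
#' @param phecode Phecode to test (must have carriers in the arm).
#' @param results Full arm results from [run_phewas()] (supplies the p-vector
#'   for BH recomputation); recomputed if `NULL`.
#' @param config An [analysis_config()].
#' @param seed Integer seed for carrier subsampling (defaults to
#'   `config$seed`).
#' @return One-row tibble: `phecode`, `arm`, `n_carriers`, `n_iterations`,
#'   `n_significant_iterations`, `robust_flag`, and a `removed_ids`
#'   list-column of the removed carriers' delivery ids.
#' @export
robustness_test <- function(units, arm, phecode, results = NULL,
                            config = analysis_config(), seed = NULL) {
  config <- as_ptb_config(config)
  arm <- normalize_arm(arm)
  if (is.null(seed)) seed <- config$seed
  if (is.null(results)) results <- run_phewas(units, arm, config)
  results <- results[results$arm == arm, , drop = FALSE]

  at <- arm_cohort(units, arm, config)
  if (config$use_covariates && anyNA(at$maternal_age_years)) {
    at <- at[!is.na(at$maternal_age_years), , drop = FALSE]
  }
  carrier <- vapply(at$phecodes, function(v) phecode %in% v, logical(1))
  carriers <- at$delivery_id[carrier]
  if (length(carriers) == 0) {
    stop("phecode ", phecode, " has no carriers in arm '", arm, "'",
         call. = FALSE)
  }

  n_iter <- min(length(carriers), config$robustness_iterations)
  removed <- if (length(carriers) <= config$robustness_iterations) {
    carriers
  } else {
    with_seed(seed, sample(carriers, config$robustness_iterations))
  }

  p_vec <- results$p_value
  idx <- match(phecode, results$phecode)
  if (is.na(idx)) {
    stop("phecode ", phecode, " not present in the arm's results", call. = FALSE)
  }

  # warm-start each leave-one-out refit from the full-cohort coefficients
  start <- NULL
  covmat_full <- if (config$use_covariates) covariate_matrix(at, config) else NULL
  full <- logit_fit(cbind(1, as.numeric(carrier), covmat_full), at$y)
  if (full$converged && !anyNA(full$coef)) start <- full$coef

  significant <- vapply(removed, function(id) {
    keep_rows <- at$delivery_id != id
    red <- at[keep_rows, , drop = FALSE]
    carrier_red <- carrier[keep_rows]
    covmat <- if (config$use_covariates) covariate_matrix(red, config) else NULL
    res <- fit_one_phecode(phecode, arm, carrier_red, red$y, covmat,
                           start = start)
    if (res$dropped_flag || is.na(res$p_value)) return(FALSE)
    p_new <- p_vec
    p_new[idx] <- res$p_value
    ok <- !is.na(p_new)
    adj <- rep(NA_real_, length(p_new))
    adj[ok] <- bh_adjust(p_new[ok])
    isTRUE(adj[idx] < config$fdr_alpha)
  }, logical(1))

  tibble::tibble(
    phecode = phecode,
    arm = arm,
    n_carriers = length(carriers),
    n_iterations = n_iter,
    n_significant_iterations = sum(significant),
    robust_flag = all(significant),
    removed_ids = list(removed)
  )
}

#' Run the stability filter over all significant phecodes of an arm
#'
#' @inheritParams robustness_test
#' @param results Adjusted full-arm results from [adjust_results()].
#' @return Tibble with one [robustness_test()] row per significant phecode
#'   (zero rows when nothing is significant).
#' @export
run_robustness <- function(units, arm, results, config = analysis_config(),
                           seed = NULL) {
  config <- as_ptb_config(config)
  arm <- normalize_arm(arm)
  arm_res <- results[results$arm == arm, , drop = FALSE]
  selected <- select_significant(arm_res, config)
  if (nrow(selected) == 0) {
    return(tibble::tibble(
      phecode = character(0), arm = character(0), n_carriers = integer(0),
      n_iterations = integer(0), n_significant_iterations = integer(0),
      robust_flag = logical(0), removed_ids = list()
    ))
  }
  purrr::map(selected$phecode, function(ph) {
    robustness_test(units, arm, ph, results = arm_res, config = config,
                    seed = seed)
  }) |>
    dplyr::bind_rows()
}

#' Intersect significant associations with the stability filter
#'
#' Returns the significant associations that survived every
#' leave-one-carrier-out iteration, annotated with the robustness percentage
#' (`100 * n_significant_iterations / n_iterations`) for results-table
#' output. Every selected phecode must carry a robustness record.
#'
#' @param results Adjusted results for one arm (or several arms bound).
#' @param robustness Output of [run_robustness()].
#' @param config An [analysis_config()].
#' @return Tibble of final (significant and robust) associations, sorted by
#'   adjusted p-value, with `robustness_pct` appended.
#' @export
significant_and_robust <- function(results, robustness,
                                   config = analysis_config()) {
  config <- as_ptb_config(config)
  selected <- select_significant(results, config)
  if (nrow(selected) == 0) return(dplyr::mutate(selected, robustness_pct = numeric(0)))

  key_sel <- paste(selected$phecode, selected$arm)
  key_rob <- paste(robustness$phecode, robustness$arm)
  missing <- setdiff(key_sel, key_rob)
  if (length(missing) > 0) {
    stop("missing robustness record(s) for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  rob <- robustness[match(key_sel, key_rob), , drop = FALSE]
  selected$robustness_pct <- 100 * rob$n_significant_iterations / rob$n_iterations
  selected$robust_flag <- rob$robust_flag
  selected[selected$robust_flag, , drop = FALSE] |>
    dplyr::arrange(.data$p_adjusted)
}
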