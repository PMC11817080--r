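#' Analysis configuration
#'
#' Collects the tunable constants of the association pipeline in one object.
#' Defaults encode the primary analysis: a 37-week term threshold, a 183-day
#' (six-month) postpartum exclusion window, FDR control at 5%, 50
#' leave-one-carrier-out stability iterations, and a 4-df natural cubic spline
#' for maternal age.
#'
#' @param term_threshold_weeks Gestational-age cutoff (weeks) separating term
#'   from preterm deliveries. Must lie in (20, 45).
#' @param postpartum_exclusion_days Days after a previous delivery during which
#'   diagnoses are not attributed to the next pregnancy.
#' @param fdr_alpha Benjamini-Hochberg false-discovery-rate threshold, in (0,1).
#' @param robustness_iterations Maximum number of leave-one-carrier-out
#'   iterations per significant phecode.
#' @param spline_df Degrees of freedom of the natural cubic spline basis for
#'   maternal age.
#' @param require_prior_diagnosis Keep only pregnancies with at least one
#'   windowed pre-conception diagnosis (the primary inclusion criterion); turn
#'   off for the sensitivity analysis that retains diagnosis-free individuals.
#' @param use_covariates Adjust for maternal age, education and insurance; turn
#'   off for the unadjusted sensitivity analysis.
#' @param include_unclassified_in_all_ptb Pool preterm deliveries that could
#'   not be classified as spontaneous or indicated into the all-PTB arm.
#' @param redaction_threshold Carrier-count threshold below which result rows
#'   are redacted in shared outputs.
#' @param seed Optional integer seed recorded in the run manifest and used for
#'   the stability filter's carrier subsampling.
#'
#' @return A list of class `ptb_config`.
#' @export
#' @examples
#' cfg <- analysis_config(fdr_alpha = 0.05)
#' cfg$term_threshold_weeks
analysis_config <- function(term_threshold_weeks = 37,
                            postpartum_exclusion_days = 183L,
                            fdr_alpha = 0.05,
                            robustness_iterations = 50L,
                            spline_df = 4L,
                            require_prior_diagnosis = TRUE,
                            use_covariates = TRUE,
                            include_unclassified_in_all_ptb = TRUE,
                            redaction_threshold = 10L,
                            seed = NULL) {
  stopifnot(
    is.numeric(term_threshold_weeks), length(term_threshold_weeks) == 1,
    term_threshold_weeks > 20, term_threshold_weeks < 45,
    is.numeric(postpartum_exclusion_days), postpartum_exclusion_days >= 0,
    is.numeric(fdr_alpha), fdr_alpha > 0, fdr_alpha < 1,
    is.numeric(robustness_iterations), robustness_iterations >= 1,
    is.numeric(spline_df), spline_df >= 1,
    is.logical(require_prior_diagnosis),
    is.logical(use_covariates),
    is.logical(include_unclassified_in_all_ptb),
    is.numeric(redaction_threshold), redaction_threshold >= 0
  )
  structure(
    list(
      term_threshold_weeks = as.numeric(term_threshold_weeks),
      postpartum_exclusion_days = as.integer(postpartum_exclusion_days),
      fdr_alpha = as.numeric(fdr_alpha),
      robustness_iterations = as.integer(robustness_iterations),
      spline_df = as.integer(spline_df),
      require_prior_diagnosis = isTRUE(require_prior_diagnosis),
      use_covariates = isTRUE(use_covariates),
      include_unclassified_in_all_ptb = isTRUE(include_unclassified_in_all_ptb),
      redaction_threshold = as.integer(redaction_threshold),
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "ptb_config"
  )
}

#' @export
print.ptb_config <- function(x, ...) {
  cat("<ptb_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-32s %s\n", nm, if (is.null(x[[nm]])) "NULL" else format(x[[nm]])))
  }
  invisible(x)
}

as_ptb_config <- function(config) {
  if (inherits(config, "ptb_config")) return(config)
  if (is.list(config)) return(do.call(analysis_config, config))
  stop("`config` must be an `analysis_config()` object or a named list",
       call. = FALSE)
}

# canonical PTB status labels accepted in delivery tables
ptb_status_levels <- function() {
  c("No", "spontaneous", "PPROM", "medically_indicated",
    "Termination_Iatrogenic", "PTL_with_TOCO_and_TERM")
}

outcome_levels <- function() {
  c("term", "spontaneous_ptb", "indicated_ptb", "unclassified_ptb", "dropped")
}

arm_levels <- function() c("indicated", "spontaneous", "all")

# accept both short arm names and the *_vs_term spellings
normalize_arm <- function(arm) {
  arm <- match.arg(sub("_vs_term$", "", arm), arm_levels())
  arm
}
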