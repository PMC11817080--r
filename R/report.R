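#' Run the full stratified association pipeline
#'
#' Executes map -> cohort -> per-arm PheWAS -> BH adjustment -> stability
#' filter -> final tables, either on user-supplied delimited-text tables or
#' on a freshly simulated cohort. When `output_dir` is given, writes the
#' included-cohort table, exclusion tally, per-arm result tables, final
#' (redacted) tables, robustness records, demographics, plot-ready
#' Manhattan/forest tables, and a machine-readable run manifest.
#'
#' @param deliveries Delivery table: a data frame or a file path for
#'   [load_delivery_table()]. Ignored when `synthetic` is supplied.
#' @param diagnoses Diagnosis-event table: data frame or file path.
#' @param map ICD-to-phecode map: a `phecode_map`, a data frame, or a file
#'   path (defaults to the bundled synthetic map for file inputs).
#' @param synthetic Optionally a [synthetic_config()] (simulated on the fly)
#'   or an existing [simulate_cohort()] result; its tables, identity map and
#'   truth are then used and recovery metrics are computed.
#' @param config An [analysis_config()].
#' @param arms Arms to analyse (subset of `indicated`, `spontaneous`, `all`).
#' @param output_dir Optional directory for all written outputs.
#' @param plots Also render minimal Manhattan/forest PNGs into `output_dir`
#'   (requires ggplot2).
#' @return A list of class `ptb_phewas_run`: `cohort`, `results` (all arms,
#'   BH-adjusted), `robustness`, `finals` (named list per arm), `dropped_hits`
#'   (significant but undefined-OR associations), `demographics`, `categories`,
#'   `manifest`, and — for synthetic inputs — `truth` and `recovery`.
#' @export
run_pipeline <- function(deliveries = NULL, diagnoses = NULL, map = NULL,
                         synthetic = NULL, config = analysis_config(),
                         arms = c("indicated", "spontaneous", "all"),
                         output_dir = NULL, plots = FALSE) {
  config <- as_ptb_config(config)
  arms <- vapply(arms, normalize_arm, character(1), USE.NAMES = FALSE)
  input_digests <- NULL
  truth <- NULL

  if (!is.null(synthetic)) {
    sim <- if (inherits(synthetic, "ptb_synth")) synthetic else simulate_cohort(synthetic)
    deliveries <- sim$deliveries
    diagnoses <- sim$diagnoses
    map <- sim$phecode_map
    truth <- sim$truth
  } else {
    if (is.character(deliveries)) {
      input_digests <- c(input_digests, unname(tools::md5sum(deliveries)))
      deliveries <- load_delivery_table(deliveries)
    }
    if (is.character(diagnoses)) {
      input_digests <- c(input_digests, unname(tools::md5sum(diagnoses)))
      diagnoses <- load_diagnosis_table(diagnoses)
    }
    if (is.null(map)) map <- phecode_map_file()
    if (is.character(map)) {
      input_digests <- c(input_digests, unname(tools::md5sum(map)))
      map <- load_phecode_map(map)
    }
  }
  if (is.null(deliveries) || is.null(diagnoses)) {
    stop("run_pipeline() needs delivery and diagnosis tables, or `synthetic`",
         call. = FALSE)
  }

  events <- map_events(diagnoses, map)
  cohort <- build_cohort(deliveries, events, config)
  units <- cohort$units
  if (nrow(units) == 0) stop("cohort stage produced no analysis units", call. = FALSE)

  results <- purrr::map(arms, function(a) run_phewas(units, a, config)) |>
    dplyr::bind_rows() |>
    adjust_results()

  robustness <- purrr::map(arms, function(a) {
    run_robustness(units, a, results, config, seed = config$seed)
  }) |>
    dplyr::bind_rows()

  finals <- lapply(stats::setNames(arms, arms), function(a) {
    significant_and_robust(results[results$arm == a, , drop = FALSE],
                           robustness, config)
  })
  dropped_hits <- dplyr::bind_rows(lapply(arms, function(a) {
    attr(select_significant(results[results$arm == a, , drop = FALSE], config),
         "dropped_undefined")
  }))

  categories <- phecode_categories(map)
  demographics <- demographics_table(units)

  manifest <- list(
    package = "ptbphewas",
    version = as.character(utils::packageVersion("ptbphewas")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config = unclass(config),
    input_md5 = input_digests,
    synthetic = !is.null(truth),
    arms = arms,
    stage_counts = list(
      input_deliveries = nrow(deliveries),
      input_diagnosis_rows = nrow(diagnoses),
      mapped_phecode_events = nrow(events),
      unmapped_diagnosis_rows = attr(events, "n_unmapped"),
      analysis_units = nrow(units),
      tested_associations = nrow(results),
      significant_and_robust = vapply(finals, nrow, integer(1))
    )
  )

  out <- structure(
    list(cohort = cohort, results = results, robustness = robustness,
         finals = finals, dropped_hits = dropped_hits,
         demographics = demographics, categories = categories,
         manifest = manifest, truth = truth),
    class = "ptb_phewas_run"
  )
  if (!is.null(truth)) out$recovery <- evaluate_recovery(out, truth)

  if (!is.null(output_dir)) write_run_outputs(out, output_dir, config, plots)
  out
}

#' @export
print.ptb_phewas_run <- function(x, ...) {
  cat("<ptb_phewas_run> ", nrow(x$cohort$units), " pregnancies, ",
      nrow(x$results), " association tests\n", sep = "")
  for (a in names(x$finals)) {
    cat("  ", a, ": ", nrow(x$finals[[a]]), " significant & robust\n", sep = "")
  }
  invisible(x)
}

write_run_outputs <- function(run, output_dir, config, plots = FALSE) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(...) file.path(output_dir, ...)

  units_flat <- run$cohort$units |>
    dplyr::mutate(phecodes = vapply(.data$phecodes, paste, character(1),
                                    collapse = ";"))
  readr::write_tsv(units_flat, path("cohort_units.tsv"), progress = FALSE)
  readr::write_tsv(run$cohort$exclusion_tally, path("exclusion_tally.tsv"),
                   progress = FALSE)
  write_result_table(annotate_results(run$results, run$categories),
                     path("association_results.tsv"))
  write_result_table(run$robustness, path("robustness_results.tsv"))
  for (a in names(run$finals)) {
    final <- annotate_results(run$finals[[a]], run$categories)
    write_result_table(redact_small_counts(final, config$redaction_threshold),
                       path(sprintf("final_hits_%s.tsv", a)))
  }
  mt <- manhattan_table(run$results, run$categories, config)
  write_result_table(mt, path("manhattan_table.tsv"))
  ft <- dplyr::bind_rows(lapply(names(run$finals), function(a) {
    dplyr::mutate(forest_table(run$finals[[a]], run$categories), arm = a)
  }))
  write_result_table(ft, path("forest_table.tsv"))
  readr::write_tsv(run$demographics$categorical, path("demographics_categorical.tsv"),
                   progress = FALSE)
  readr::write_tsv(run$demographics$continuous, path("demographics_continuous.tsv"),
                   progress = FALSE)
  readr::write_tsv(run$demographics$age_comparisons, path("demographics_age_tests.tsv"),
                   progress = FALSE)
  jsonlite::write_json(run$manifest, path("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")

  if (plots && requireNamespace("ggplot2", quietly = TRUE)) {
    ggplot2::ggsave(path("manhattan.png"), plot_manhattan(mt, config),
                    width = 9, height = 4, dpi = 150)
    if (nrow(ft) > 0) {
      ggplot2::ggsave(path("forest.png"), plot_forest(ft),
                      width = 7, height = 1 + 0.25 * nrow(ft), dpi = 150)
    }
  }
  invisible(output_dir)
}

annotate_results <- function(results, categories) {
  if (is.null(categories) || nrow(results) == 0) return(results)
  dplyr::left_join(results, categories, by = "phecode")
}

#' Plot-ready Manhattan table
#'
#' One row per tested phecode per arm with `-log10` adjusted p-values,
#' organ-system category, and a status flag (`significant`, `not_significant`
#' or `dropped` for undefined/unstable fits), sorted by category then
#' phecode.
#'
#' @param results Adjusted results from [adjust_results()].
#' @param categories Phecode category lookup from [phecode_categories()].
#' @param config An [analysis_config()].
#' @return Tibble with columns `arm`, `phecode`, `phenotype`, `category`,
#'   `neg_log10_p_adjusted`, `status`.
#' @export
manhattan_table <- function(results, categories = NULL,
                            config = analysis_config()) {
  config <- as_ptb_config(config)
  out <- annotate_results(results, categories)
  if (!"phenotype" %in% names(out)) out$phenotype <- NA_character_
  if (!"category" %in% names(out)) out$category <- NA_character_
  out |>
    dplyr::mutate(
      neg_log10_p_adjusted = -log10(.data$p_adjusted),
      status = dplyr::case_when(
        .data$dropped_flag ~ "dropped",
        !is.na(.data$p_adjusted) & .data$p_adjusted < config$fdr_alpha ~ "significant",
        TRUE ~ "not_significant"
      )
    ) |>
    dplyr::select("arm", "phecode", "phenotype", "category",
                  "neg_log10_p_adjusted", "status") |>
    dplyr::arrange(.data$arm, .data$category, .data$phecode)
}

#' Plot-ready forest table
#'
#' Final hits with defined odds ratios, sorted by OR descending.
#'
#' @param final A final table from [significant_and_robust()].
#' @param categories Phecode category lookup.
#' @return Tibble with `phecode`, `phenotype`, `category`, `odds_ratio`,
#'   `ci_low`, `ci_high`.
#' @export
forest_table <- function(final, categories = NULL) {
  out <- annotate_results(final, categories)
  if (!"phenotype" %in% names(out)) out$phenotype <- NA_character_
  if (!"category" %in% names(out)) out$category <- NA_character_
  out |>
    dplyr::filter(!is.na(.data$odds_ratio)) |>
    dplyr::arrange(dplyr::desc(.data$odds_ratio)) |>
    dplyr::select("phecode", "phenotype", "category", "odds_ratio",
                  "ci_low", "ci_high")
}

#' Demographics summary by outcome group
#'
#' Table-1-style summary per outcome group (indicated, spontaneous, all
#' preterm, term, overall): counts and percentages for education and
#' insurance categories, mean/SD/median/min/max for maternal age and
#' per-pregnancy diagnosis counts, and two-sided Mann-Whitney (Wilcoxon
#' rank-sum) p-values comparing maternal age between each preterm group and
#' term. Comparisons are skipped (NA) for empty groups.
#'
#' @param units Cohort units (or a `ptb_cohort`).
#' @return A list with tibbles `categorical`, `continuous`,
#'   `age_comparisons`.
#' @export
demographics_table <- function(units) {
  units <- if (inherits(units, "ptb_cohort")) units$units else units
  groups <- list(
    indicated = units[units$outcome == "indicated_ptb", , drop = FALSE],
    spontaneous = units[units$outcome == "spontaneous_ptb", , drop = FALSE],
    all_preterm = units[units$outcome != "term", , drop = FALSE],
    term = units[units$outcome == "term", , drop = FALSE],
    overall = units
  )

  categorical <- purrr::imap(groups, function(g, nm) {
    dplyr::bind_rows(
      tibble::tibble(variable = "education",
                     level = levels(units$education_category),
                     n = as.integer(table(g$education_category))),
      tibble::tibble(variable = "insurance",
                     level = levels(units$insurance_category),
                     n = as.integer(table(g$insurance_category)))
    ) |>
      dplyr::group_by(.data$variable) |>
      dplyr::mutate(group = nm, group_n = nrow(g),
                    pct = ifelse(nrow(g) > 0, 100 * .data$n / nrow(g), 0)) |>
      dplyr::ungroup()
  }) |>
    dplyr::bind_rows() |>
    dplyr::select("group", "group_n", "variable", "level", "n", "pct")

  summarize_num <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) {
      return(tibble::tibble(n = 0L, mean = NA_real_, sd = NA_real_,
                            median = NA_real_, min = NA_real_, max = NA_real_))
    }
    tibble::tibble(n = length(x), mean = mean(x), sd = sd(x),
                   median = median(x), min = min(x), max = max(x))
  }
  continuous <- purrr::imap(groups, function(g, nm) {
    dplyr::bind_rows(
      dplyr::mutate(summarize_num(g$maternal_age_years),
                    variable = "maternal_age_years"),
      dplyr::mutate(summarize_num(g$n_phecodes), variable = "n_phecodes")
    ) |>
      dplyr::mutate(group = nm)
  }) |>
    dplyr::bind_rows() |>
    dplyr::select("group", "variable", "n", "mean", "sd", "median", "min", "max")

  compare <- function(a, b) {
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) == 0 || length(b) == 0) return(NA_real_)
    suppressWarnings(wilcox.test(a, b, alternative = "two.sided")$p.value)
  }
  age_comparisons <- tibble::tibble(
    comparison = c("indicated_vs_term", "spontaneous_vs_term",
                   "all_preterm_vs_term", "indicated_vs_spontaneous"),
    p_value = c(
      compare(groups$indicated$maternal_age_years, groups$term$maternal_age_years),
      compare(groups$spontaneous$maternal_age_years, groups$term$maternal_age_years),
      compare(groups$all_preterm$maternal_age_years, groups$term$maternal_age_years),
      compare(groups$indicated$maternal_age_years,
              groups$spontaneous$maternal_age_years)
    )
  )

  list(categorical = categorical, continuous = continuous,
       age_comparisons = age_comparisons)
}

#' Redact small-count rows from a result table
#'
#' Privacy guard for shared outputs: in rows where any carrier count
#' (`n_case_with`, `n_control_with`) is below the threshold, counts, odds
#' ratio, confidence bounds and p-values are replaced with `NA` and the row
#' is flagged in a `redacted` column. A threshold of 0 is the identity
#' transform.
#'
#' @param table Result table containing carrier-count columns.
#' @param threshold Minimum carrier count to escape redaction.
#' @return The table with redacted cells set to `NA` and a `redacted` flag.
#' @export
redact_small_counts <- function(table, threshold) {
  count_cols <- intersect(c("n_case_with", "n_control_with"), names(table))
  if (length(count_cols) == 0) stop("table has no carrier-count columns", call. = FALSE)
  if (nrow(table) == 0) return(dplyr::mutate(table, redacted = logical(0)))
  mask <- Reduce(`|`, lapply(count_cols, function(cc) table[[cc]] < threshold))
  value_cols <- intersect(
    c(count_cols, "odds_ratio", "ci_low", "ci_high", "log_or", "se_log_or",
      "p_value", "p_adjusted"),
    names(table)
  )
  for (vc in value_cols) table[[vc]][mask] <- NA
  table$redacted <- mask
  table
}

#' Minimal Manhattan plot
#' @param mt A [manhattan_table()].
#' @param config An [analysis_config()].
#' @return A ggplot object.
#' @export
plot_manhattan <- function(mt, config = analysis_config()) {
  config <- as_ptb_config(config)
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  ggplot2::ggplot(mt[!is.na(mt$neg_log10_p_adjusted), , drop = FALSE],
                  ggplot2::aes(x = .data$phecode, y = .data$neg_log10_p_adjusted,
                               colour = .data$category)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(config$fdr_alpha), linetype = 2) +
    ggplot2::facet_wrap(~arm, ncol = 1) +
    ggplot2::labs(x = "phecode", y = expression(-log[10]~adjusted~p)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   legend.position = "none")
}

#' Minimal forest plot
#' @param ft A [forest_table()] (optionally with an `arm` column).
#' @return A ggplot object.
#' @export
plot_forest <- function(ft) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  lab <- ifelse(is.na(ft$phenotype), ft$phecode, ft$phenotype)
  ft$label <- factor(lab, levels = rev(unique(lab)))
  ggplot2::ggplot(ft, ggplot2::aes(x = .data$odds_ratio, y = .data$label)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high), height = 0.2) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}
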