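#' Read a delivery table
#'
#' Reads a delimited text file (comma for `.csv`, tab for `.tsv`/`.txt`) with
#' one row per delivery. Required columns: `person_id`, `delivery_id`,
#' `delivery_date` (ISO-8601), `gestational_age_weeks`, `plurality`,
#' `ptb_status_label`, `maternal_age_years`, `education_years`,
#' `private_insurance`. An optional `race_label` column is carried through for
#' descriptive summaries only. Dates and gestational ages may be missing
#' (such deliveries are excluded, with a tally, during selection), but
#' recorded gestational ages must lie in (0, 45] and recorded maternal ages
#' in [10, 60].
#'
#' @param path Path to the file.
#' @return Tibble of delivery records with typed columns.
#' @export
load_delivery_table <- function(path) {
  if (!file.exists(path)) stop("delivery table not found: ", path, call. = FALSE)
  raw <- read_delim_auto(path)
  required <- c("person_id", "delivery_id", "delivery_date",
                "gestational_age_weeks", "plurality", "ptb_status_label",
                "maternal_age_years", "education_years", "private_insurance")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("delivery table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  d <- tibble::as_tibble(raw)
  d$delivery_date <- as.Date(d$delivery_date)
  for (col in c("gestational_age_weeks", "maternal_age_years", "education_years")) {
    d[[col]] <- suppressWarnings(as.numeric(d[[col]]))
  }
  d$plurality <- suppressWarnings(as.integer(d$plurality))

  ga <- d$gestational_age_weeks
  if (any(!is.na(ga) & (ga <= 0 | ga > 45))) {
    stop("gestational ages outside (0, 45] weeks in delivery table", call. = FALSE)
  }
  age <- d$maternal_age_years
  if (any(!is.na(age) & (age < 10 | age > 60))) {
    stop("maternal ages outside [10, 60] years in delivery table", call. = FALSE)
  }
  bad <- setdiff(unique(d$ptb_status_label), c(ptb_status_levels(), NA))
  if (length(bad) > 0) {
    stop("unknown PTB status label(s) in delivery table: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  d
}

#' Read a diagnosis-event table
#'
#' Reads a delimited text file with one row per coded diagnosis event.
#' Required columns: `person_id`, `code`, `code_system`, `event_date`
#' (ISO-8601).
#'
#' @param path Path to the file.
#' @return Tibble of diagnosis events.
#' @export
load_diagnosis_table <- function(path) {
  if (!file.exists(path)) stop("diagnosis table not found: ", path, call. = FALSE)
  raw <- read_delim_auto(path)
  required <- c("person_id", "code", "code_system", "event_date")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("diagnosis table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  d <- tibble::as_tibble(raw)
  d$event_date <- as.Date(d$event_date)
  d
}

write_result_table <- function(x, path) {
  # list-columns (e.g. removed carrier ids) are serialized as ';'-joined strings
  x <- dplyr::mutate(tibble::as_tibble(x), dplyr::across(
    dplyr::where(is.list),
    function(col) vapply(col, function(v) paste(as.character(v), collapse = ";"),
                         character(1))
  ))
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}
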