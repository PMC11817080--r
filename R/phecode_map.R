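#' Path to the bundled synthetic ICD-to-phecode map
#'
#' The package ships a small hand-built map (~60 ICD-9-CM/ICD-10-CM codes)
#' covering essential hypertension (401.1), type 1 and type 2 diabetes
#' (250.1, 250.2), chronic kidney disease (585) and assorted filler
#' conditions, so examples and tests run without any download. It is a
#' synthetic teaching map, not the community phecode map.
#'
#' @return File path of the bundled CSV.
#' @export
phecode_map_file <- function() {
  system.file("extdata", "phecode_map_synthetic.csv", package = "ptbphewas",
              mustWork = TRUE)
}

read_delim_auto <- function(path) {
  delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE, trim_ws = TRUE,
                    col_types = readr::cols(.default = readr::col_character()))
}

#' Load an ICD-to-phecode mapping table
#'
#' Reads a delimited text file (comma for `.csv`, tab for `.tsv`/`.txt`)
#' mapping ICD diagnosis codes to phecodes. Two layouts are accepted:
#'
#' * long: columns `code`, `code_system`, `phecode` (optionally `phenotype`,
#'   `category`), one row per (code, system) pair;
#' * community-map style: a column named `icd9` or `icd10` (or
#'   `ICD9`/`ICD10`/`icd9cm`/`icd10cm`) together with `phecode`/`PheCode`,
#'   with the code system implied by the column name.
#'
#' The mapping must be many-to-one per (code, code_system): duplicated pairs
#' carrying conflicting phecodes raise an integrity error. Phecode strings
#' must match `digits[.digits]`.
#'
#' @param path Path to the mapping file.
#' @return A tibble of class `phecode_map` with columns `code`, `code_system`,
#'   `phecode` and, when present in the source, `phenotype` and `category`.
#'   The source path is kept in the `provenance` attribute.
#' @export
#' @examples
#' map <- load_phecode_map(phecode_map_file())
#' head(map)
load_phecode_map <- function(path) {
  if (!file.exists(path)) stop("phecode map file not found: ", path, call. = FALSE)
  raw <- read_delim_auto(path)
  names(raw) <- tolower(names(raw))

  icd_col <- intersect(names(raw), c("icd9", "icd9cm", "icd10", "icd10cm"))
  if (length(icd_col) == 1 && !"code" %in% names(raw)) {
    system <- if (grepl("^icd9", icd_col)) "ICD9CM" else "ICD10CM"
    raw <- dplyr::rename(raw, code = dplyr::all_of(icd_col))
    raw$code_system <- system
  }
  needed <- c("code", "code_system", "phecode")
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0) {
    stop("phecode map is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }

  keep <- intersect(c(needed, "phenotype", "category"), names(raw))
  map <- dplyr::distinct(tibble::as_tibble(raw[keep]))
  map <- map[!is.na(map$code) & nzchar(map$code), , drop = FALSE]

  bad <- map$phecode[!grepl("^[0-9]+(\\.[0-9]+)?$", map$phecode)]
  if (length(bad) > 0) {
    stop("malformed phecode string(s) in map: ",
         paste(unique(head(bad, 5)), collapse = ", "), call. = FALSE)
  }

  dup <- dplyr::count(map, .data$code, .data$code_system)
  dup <- dup[dup$n > 1, , drop = FALSE]
  if (nrow(dup) > 0) {
    stop("conflicting phecode assignments for ", nrow(dup),
         " (code, code_system) pair(s), e.g. ", dup$code[1], call. = FALSE)
  }

  if (nrow(map) == 0) warning("phecode map contains no entries", call. = FALSE)
  message("loaded phecode map: ", nrow(map), " entries from ", basename(path))
  attr(map, "provenance") <- normalizePath(path)
  class(map) <- c("phecode_map", class(map))
  map
}

#' Truncate phecodes after the first decimal digit
#'
#' Coarsens phecodes to subgroup granularity: at most one digit is kept after
#' the decimal point ("250.21" becomes "250.2"); integer phecodes are
#' unchanged. The operation is idempotent.
#'
#' @param phecode Character vector of phecode strings (`digits[.digits]`).
#' @return Character vector of truncated phecodes.
#' @export
#' @examples
#' truncate_phecode(c("250.21", "401", "008.5"))
truncate_phecode <- function(phecode) {
  phecode <- as.character(phecode)
  ok <- grepl("^[0-9]+(\\.[0-9]+)?$", phecode)
  if (any(!ok)) {
    stop("malformed phecode string(s): ",
         paste(unique(head(phecode[!ok], 5)), collapse = ", "), call. = FALSE)
  }
  sub("^([0-9]+\\.[0-9])[0-9]*$", "\\1", phecode)
}

#' Map diagnosis events to phecode events
#'
#' Joins a diagnosis-event table to a phecode map on (code, code_system),
#' truncates the resulting phecodes to one post-decimal digit, and
#' deduplicates to one row per (person, phecode, date). Events whose code has
#' no map entry are dropped (by design — they fall outside the tested
#' phenotype universe) and the dropped count is reported via `message()` and
#' the `n_unmapped` attribute.
#'
#' @param events Data frame with columns `person_id`, `code`, `code_system`,
#'   `event_date` (Date or ISO-8601 string).
#' @param map A `phecode_map` from [load_phecode_map()], or any data frame
#'   with columns `code`, `code_system`, `phecode`.
#' @return Tibble with columns `person_id`, `phecode`, `event_date`.
#' @export
map_events <- function(events, map) {
  events <- tibble::as_tibble(events)
  required <- c("person_id", "code", "code_system", "event_date")
  missing <- setdiff(required, names(events))
  if (length(missing) > 0) {
    stop("diagnosis table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  events$event_date <- as.Date(events$event_date)
  if (anyNA(events$event_date)) {
    stop("diagnosis table contains missing or unparseable event dates", call. = FALSE)
  }
  if (any(is.na(events$code) | !nzchar(events$code))) {
    stop("diagnosis table contains empty diagnosis codes", call. = FALSE)
  }

  mapped <- dplyr::inner_join(
    events,
    dplyr::select(tibble::as_tibble(map), "code", "code_system", "phecode"),
    by = c("code", "code_system")
  )
  n_unmapped <- nrow(events) - nrow(mapped)
  out <- mapped |>
    dplyr::transmute(
      person_id = .data$person_id,
      phecode = truncate_phecode(.data$phecode),
      event_date = .data$event_date
    ) |>
    dplyr::distinct()
  message("mapped ", nrow(out), " phecode events (", n_unmapped,
          " unmappable diagnosis rows dropped)")
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Phecode phenotype/category lookup
#'
#' Returns the phenotype label and organ-system category for each phecode in
#' a map, for annotating Manhattan/forest tables. Categories cover only the
#' codes present in the supplied map.
#'
#' @param map A `phecode_map` (defaults to the bundled synthetic map).
#' @return Tibble with columns `phecode`, `phenotype`, `category` (one row
#'   per truncated phecode).
#' @export
phecode_categories <- function(map = load_phecode_map(phecode_map_file())) {
  map <- tibble::as_tibble(map)
  if (!"phenotype" %in% names(map)) map$phenotype <- NA_character_
  if (!"category" %in% names(map)) map$category <- NA_character_
  map |>
    dplyr::mutate(phecode = truncate_phecode(.data$phecode)) |>
    dplyr::distinct(.data$phecode, .keep_all = TRUE) |>
    dplyr::select("phecode", "phenotype", "category")
}
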