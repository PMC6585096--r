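#' Read and write cohort CSV files
#'
#' A cohort is persisted as two CSV files under a directory: `patients.csv`
#' (`patient_id`, `age_2012`, `gender`, `ethnicity`, `death_date` ISO-8601 or
#' empty, `chronic_conditions` semicolon-joined, `serious_acute` 0/1,
#' `end_of_life_condition` 0/1) and `encounters.csv` (`patient_id`, `date`
#' ISO-8601, `kind` in ED/SOC/INPATIENT). The round trip is lossless,
#' including absent death dates, and writing the same cohort twice produces
#' byte-identical files.
#'
#' @param patients,encounters cohort tibbles as produced by
#'   [generate_cohort()].
#' @param dir directory to write into (created if needed).
#' @return `write_cohort()` returns the directory invisibly; `read_cohort()`
#'   a list with validated `patients` and `encounters` tibbles.
#' @export
write_cohort <- function(patients, encounters, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pat <- patients |>
    mutate(death_date = format(.data$death_date, "%Y-%m-%d"),
           serious_acute = as.integer(.data$serious_acute),
           end_of_life_condition = as.integer(.data$end_of_life_condition))
  readr::write_csv(pat, file.path(dir, "patients.csv"), na = "")
  enc <- encounters |> mutate(date = format(.data$date, "%Y-%m-%d"))
  readr::write_csv(enc, file.path(dir, "encounters.csv"), na = "")
  invisible(dir)
}

format_error <- function(msg) abort(msg, class = "popseg_error_format")

check_iso_dates <- function(x, what, allow_empty = FALSE) {
  x <- ifelse(is.na(x), "", x)
  iso <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  empty <- x == ""
  bad <- !iso & !(allow_empty & empty)
  if (any(bad)) {
    row <- which(bad)[1]
    format_error(sprintf(
      "%s row %d: date '%s' is not ISO-8601 (expected YYYY-MM-DD)",
      what, row, x[row]))
  }
  parsed <- as.Date(ifelse(empty, NA_character_, x), format = "%Y-%m-%d")
  invalid <- !empty & is.na(parsed)
  if (any(invalid)) {
    row <- which(invalid)[1]
    format_error(sprintf("%s row %d: '%s' is not a valid calendar date",
                         what, row, x[row]))
  }
  parsed
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  ppath <- file.path(dir, "patients.csv")
  epath <- file.path(dir, "encounters.csv")
  for (p in c(ppath, epath)) {
    if (!file.exists(p)) format_error(paste0("missing cohort file: ", p))
  }
  pat <- readr::read_csv(
    ppath, na = character(), show_col_types = FALSE,
    col_types = readr::cols(.default = readr::col_character(),
                            age_2012 = readr::col_integer(),
                            serious_acute = readr::col_integer(),
                            end_of_life_condition = readr::col_integer()))
  need <- c("patient_id", "age_2012", "gender", "ethnicity", "death_date",
            "chronic_conditions", "serious_acute", "end_of_life_condition")
  miss <- setdiff(need, names(pat))
  if (length(miss) > 0) {
    format_error(paste0("patients.csv missing column(s): ",
                        paste(miss, collapse = ", ")))
  }
  pat <- pat |>
    mutate(death_date = check_iso_dates(.data$death_date, "patients.csv",
                                        allow_empty = TRUE),
           serious_acute = .data$serious_acute == 1L,
           end_of_life_condition = .data$end_of_life_condition == 1L)

  enc <- readr::read_csv(
    epath, na = character(), show_col_types = FALSE,
    col_types = readr::cols(.default = readr::col_character()))
  miss <- setdiff(c("patient_id", "date", "kind"), names(enc))
  if (length(miss) > 0) {
    format_error(paste0("encounters.csv missing column(s): ",
                        paste(miss, collapse = ", ")))
  }
  bad <- !enc$kind %in% encounter_kinds()
  if (any(bad)) {
    row <- which(bad)[1]
    format_error(sprintf(
      "encounters.csv row %d: unknown encounter kind '%s' (expected ED, SOC or INPATIENT)",
      row, enc$kind[row]))
  }
  enc <- enc |> mutate(date = check_iso_dates(.data$date, "encounters.csv"))
  list(patients = pat, encounters = enc)
}
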