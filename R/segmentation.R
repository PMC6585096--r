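#' Segmentation rule set
#'
#' The six segments are assigned by a precedence-ordered rule set evaluated on
#' baseline-year data. Default predicates, checked in precedence order, label
#' a patient with the first segment whose predicate holds:
#'
#' * `END_OF_LIFE`: the end-of-life condition flag is set.
#' * `COMPLEX_CHRONIC_FREQ`: at least `complex_min_chronic_count` recognized
#'   chronic condition categories **and** at least
#'   `frequent_admission_threshold` inpatient admissions in the baseline
#'   window (the published proxy for high-cost users is 3+ admissions in the
#'   past 12 months).
#' * `COMPLEX_CHRONIC_NO_FREQ`: the same chronic criterion with fewer
#'   admissions.
#' * `SERIOUS_ACUTE`: the serious-acute condition flag is set.
#' * `STABLE_CHRONIC`: at least one recognized chronic condition category.
#' * `MOSTLY_HEALTHY`: always true; must be the final catch-all.
#'
#' The default precedence is severity-descending; the framework requires
#' non-overlap, and any permutation keeping `MOSTLY_HEALTHY` last is allowed.
#'
#' @param chronic_vocabulary recognized chronic condition category ids.
#' @param complex_min_chronic_count chronic categories needed for the Complex
#'   Chronic segments (default 2).
#' @param frequent_admission_threshold admissions defining a frequent
#'   admitter (default 3).
#' @param precedence permutation of [segment_levels()] ending in
#'   `MOSTLY_HEALTHY`.
#' @param baseline_window length-2 Date vector, the closed baseline interval
#'   (default calendar year 2012, the 365-day lookback from study entry).
#' @return A list of class `popseg_rules`.
#' @export
#' @examples
#' rules <- default_rules()
#' rules$frequent_admission_threshold
default_rules <- function(chronic_vocabulary = default_chronic_vocabulary(),
                          complex_min_chronic_count = 2L,
                          frequent_admission_threshold = 3L,
                          precedence = c("END_OF_LIFE", "COMPLEX_CHRONIC_FREQ",
                                         "COMPLEX_CHRONIC_NO_FREQ",
                                         "SERIOUS_ACUTE", "STABLE_CHRONIC",
                                         "MOSTLY_HEALTHY"),
                          baseline_window = c(study_dates()$baseline_start,
                                              study_dates()$baseline_end)) {
  rules <- structure(
    list(chronic_vocabulary = chronic_vocabulary,
         complex_min_chronic_count = as.integer(complex_min_chronic_count),
         frequent_admission_threshold = as.integer(frequent_admission_threshold),
         precedence = precedence,
         baseline_window = as.Date(baseline_window)),
    class = "popseg_rules")
  validate_rules(rules)
}

validate_rules <- function(rules) {
  if (rules$frequent_admission_threshold < 1L) {
    config_error("frequent_admission_threshold must be >= 1")
  }
  if (rules$complex_min_chronic_count < 1L) {
    config_error("complex_min_chronic_count must be >= 1")
  }
  p <- rules$precedence
  if (!identical(sort(p), sort(segment_levels()))) {
    config_error("precedence must be a permutation of the six segment codes")
  }
  if (p[length(p)] != "MOSTLY_HEALTHY") {
    config_error("precedence must end with MOSTLY_HEALTHY as the final catch-all")
  }
  if (length(rules$baseline_window) != 2 ||
      rules$baseline_window[1] > rules$baseline_window[2]) {
    config_error("baseline_window must be an ordered pair of dates")
  }
  rules
}

#' Read / write a rule set as YAML
#' @param rules a `popseg_rules` object.
#' @param path file path.
#' @return `write_rules()` the path invisibly; `read_rules()` a validated
#'   rule set.
#' @export
write_rules <- function(rules, path) {
  yaml::write_yaml(list(
    chronic_vocabulary = rules$chronic_vocabulary,
    complex_min_chronic_count = rules$complex_min_chronic_count,
    frequent_admission_threshold = rules$frequent_admission_threshold,
    precedence = rules$precedence,
    baseline_window = format(rules$baseline_window, "%Y-%m-%d")
  ), path)
  invisible(path)
}

#' @rdname write_rules
#' @export
read_rules <- function(path) {
  raw <- yaml::read_yaml(path)
  default_rules(
    chronic_vocabulary = raw$chronic_vocabulary,
    complex_min_chronic_count = raw$complex_min_chronic_count,
    frequent_admission_threshold = raw$frequent_admission_threshold,
    precedence = raw$precedence,
    baseline_window = as.Date(raw$baseline_window)
  )
}

#' Filter the eligible study population
#'
#' Keeps adult patients (age 21 or older in the baseline year) who used
#' healthcare services in the baseline year, i.e. have at least one encounter
#' of any kind dated within the baseline window.
#'
#' @param patients patient tibble.
#' @param encounters encounter tibble.
#' @param rules a [default_rules()] rule set (supplies the baseline window).
#' @return The eligible subset of `patients`.
#' @export
filter_eligible <- function(patients, encounters, rules = default_rules()) {
  if (anyNA(patients$age_2012)) {
    data_error("age_2012 is missing for one or more patients")
  }
  w <- rules$baseline_window
  active <- encounters |>
    filter(.data$date >= w[1], .data$date <= w[2]) |>
    pull("patient_id") |>
    unique()
  patients |>
    filter(.data$age_2012 >= 21L, .data$patient_id %in% active)
}

#' Count inpatient admissions in a window
#'
#' @param encounters encounter tibble (any patients).
#' @param window closed Date interval, length 2.
#' @return Integer count of `INPATIENT` encounters dated in the window; ED
#'   and SOC encounters never count.
#' @export
#' @examples
#' enc <- tibble::tibble(
#'   patient_id = "a",
#'   date = as.Date(c("2012-03-01", "2012-06-01", "2011-12-31")),
#'   kind = c("INPATIENT", "INPATIENT", "INPATIENT"))
#' count_admissions_in_window(enc, as.Date(c("2012-01-01", "2012-12-31")))
count_admissions_in_window <- function(encounters,
                                       window = c(study_dates()$baseline_start,
                                                  study_dates()$baseline_end)) {
  window <- as.Date(window)
  if (length(window) != 2 || window[1] > window[2]) {
    config_error("window must be an ordered pair of dates")
  }
  sum(encounters$kind == "INPATIENT" &
        encounters$date >= window[1] & encounters$date <= window[2])
}

n_recognized_chronic <- function(chronic_conditions, vocabulary) {
  vapply(strsplit(ifelse(is.na(chronic_conditions), "", chronic_conditions),
                  ";", fixed = TRUE),
         function(cc) length(intersect(cc[cc != ""], vocabulary)),
         integer(1))
}

segment_predicates <- function(n_chronic, n_admissions, serious_acute,
                               end_of_life, rules) {
  th <- rules$frequent_admission_threshold
  mc <- rules$complex_min_chronic_count
  list(
    END_OF_LIFE             = end_of_life,
    COMPLEX_CHRONIC_FREQ    = n_chronic >= mc & n_admissions >= th,
    COMPLEX_CHRONIC_NO_FREQ = n_chronic >= mc & n_admissions < th,
    SERIOUS_ACUTE           = serious_acute,
    STABLE_CHRONIC          = n_chronic >= 1L,
    MOSTLY_HEALTHY          = rep(TRUE, length(n_chronic))
  )
}

#' Classify one patient
#'
#' Applies the precedence-ordered rules to a single patient's baseline record
#' and encounters. [segment_cohort()] is the vectorised equivalent.
#'
#' @param patient one-row patient tibble.
#' @param encounters_2012 that patient's encounters (only those inside the
#'   rules' baseline window are used).
#' @param rules a [default_rules()] rule set.
#' @return A length-1 segment factor.
#' @export
classify_patient <- function(patient, encounters_2012, rules = default_rules()) {
  stopifnot(nrow(patient) == 1)
  seg <- segment_cohort(patient, encounters_2012, rules)
  seg$segment[[1]]
}

#' Segment a cohort
#'
#' Assigns every patient exactly one of the six segments (a partition): for
#' each patient the predicates are evaluated in precedence order and the
#' first that holds gives the label; `MOSTLY_HEALTHY` is the final catch-all,
#' so no patient is left unlabeled.
#'
#' @param patients eligible patient tibble (unique `patient_id`).
#' @param encounters encounter tibble for (at least) those patients.
#' @param rules a [default_rules()] rule set.
#' @return Tibble with `patient_id` and `segment`, one row per patient.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 50, seed = 3))
#' seg <- segment_cohort(cohort$patients, cohort$encounters)
#' all(seg$segment == cohort$true_segments$segment)
segment_cohort <- function(patients, encounters, rules = default_rules()) {
  rules <- validate_rules(rules)
  if (anyDuplicated(patients$patient_id)) {
    data_error(paste0("duplicate patient_id: ",
                      patients$patient_id[duplicated(patients$patient_id)][1]))
  }
  n <- nrow(patients)
  if (n == 0L) {
    return(tibble(patient_id = character(), segment = as_segment(character())))
  }
  w <- rules$baseline_window
  adm <- encounters |>
    filter(.data$kind == "INPATIENT", .data$date >= w[1], .data$date <= w[2]) |>
    count(.data$patient_id, name = "n_admissions")
  n_adm <- adm$n_admissions[match(patients$patient_id, adm$patient_id)]
  n_adm[is.na(n_adm)] <- 0L
  n_chr <- n_recognized_chronic(patients$chronic_conditions,
                                rules$chronic_vocabulary)
  preds <- segment_predicates(n_chr, n_adm,
                              isTRUE_vec(patients$serious_acute),
                              isTRUE_vec(patients$end_of_life_condition),
                              rules)
  label <- rep(NA_character_, n)
  for (seg in rules$precedence) {
    hit <- is.na(label) & preds[[seg]]
    label[hit] <- seg
  }
  tibble(patient_id = patients$patient_id, segment = as_segment(label))
}

isTRUE_vec <- function(x) !is.na(x) & x
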