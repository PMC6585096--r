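#' Synthetic-cohort generator configuration
#'
#' Builds a validated configuration for [generate_cohort()]. Every default is
#' calibrated to the published reference-cohort summaries (see
#' [reference_segment_counts()]): segment mixing proportions, per-segment
#' demographic marginals, baseline-2012 encounter means, 2013-2015 follow-up
#' encounter rates per patient-day, per-outcome overdispersion and per-segment
#' yearly survival.
#'
#' @param n_patients number of patients to generate.
#' @param segment_proportions named numeric vector over [segment_levels()],
#'   nonnegative and summing to 1 (within 1e-9).
#' @param demographics tibble with columns `segment`, `age_mean`, `age_sd`,
#'   `p_male`, `p_chinese`, `p_malay`, `p_indian`, `p_others` (one row per
#'   segment). Ethnicity fractions are renormalised to sum to 1.
#' @param baseline_rates tibble with columns `segment`, `ED`, `SOC`,
#'   `INPATIENT`: expected baseline-year (2012) encounter counts per patient.
#' @param followup_rates tibble with columns `segment`, `ED`, `SOC`,
#'   `INPATIENT`: expected 2013-2015 encounters per patient-day.
#' @param dispersion named numeric vector of NB2 overdispersion parameters
#'   (alpha, variance = mu + alpha * mu^2) per outcome; 0 means Poisson.
#' @param yearly_survival named list over segments, each a length-3
#'   nonincreasing vector in (0, 1]: survival probability at the end of
#'   follow-up years 1, 2 and 3 (days 365, 730, 1094).
#' @param seed master integer seed; all generator randomness derives from it.
#' @return A validated list of class `popseg_config`.
#' @export
#' @examples
#' cfg <- cohort_config(n_patients = 500, seed = 7)
#' cfg$segment_proportions
cohort_config <- function(n_patients,
                          segment_proportions = default_segment_proportions(),
                          demographics = reference_demographics(),
                          baseline_rates = default_baseline_rates(),
                          followup_rates = default_followup_rates(),
                          dispersion = c(ED = 3, SOC = 3, INPATIENT = 3),
                          yearly_survival = reference_yearly_survival(),
                          seed = 1L) {
  cfg <- structure(
    list(n_patients = n_patients,
         segment_proportions = segment_proportions,
         demographics = as_tibble(demographics),
         baseline_rates = as_tibble(baseline_rates),
         followup_rates = as_tibble(followup_rates),
         dispersion = dispersion,
         yearly_survival = yearly_survival,
         seed = as.integer(seed)),
    class = "popseg_config")
  validate_config(cfg)
}

#' @rdname cohort_config
#' @export
default_segment_proportions <- function() {
  counts <- reference_segment_counts()
  setNames(c(0.588, 0.245, 0.053, 0.107, 0.005, 0.002),
           as.character(counts$segment))
}

#' @rdname cohort_config
#' @export
default_followup_rates <- function() {
  reference_utilization() |>
    mutate(rate_per_day = .data$rate_per_1000_days / 1000) |>
    select("segment", "outcome", "rate_per_day") |>
    tidyr::pivot_wider(names_from = "outcome", values_from = "rate_per_day") |>
    arrange(.data$segment)
}

#' @rdname cohort_config
#' @export
default_baseline_rates <- function() {
  # Baseline-2012 encounter means per patient, consistent with the reference
  # cohort's baseline medians/IQRs and %-with-any. Admission means for the
  # frequent-admitter segment sit above the >= 3 defining threshold; all other
  # segments stay below it.
  tibble(
    segment   = as_segment(segment_levels()),
    ED        = c(0.05, 0.08, 0.09, 0.35, 3.0, 0.35),
    SOC       = c(2.0, 1.6, 8.0, 8.0, 23.0, 27.0),
    INPATIENT = c(0.04, 0.06, 0.12, 0.30, 4.2, 0.60)
  )
}

config_error <- function(msg) abort(msg, class = "popseg_error_config")

validate_config <- function(cfg) {
  if (!is.numeric(cfg$n_patients) || length(cfg$n_patients) != 1 ||
      is.na(cfg$n_patients) || cfg$n_patients < 0 ||
      cfg$n_patients != floor(cfg$n_patients)) {
    config_error("n_patients must be a single nonnegative integer")
  }
  cfg$n_patients <- as.integer(cfg$n_patients)

  p <- cfg$segment_proportions
  if (length(p) != 6 || !setequal(names(p), segment_levels())) {
    config_error("segment_proportions must be named over the six segment codes")
  }
  p <- p[segment_levels()]
  if (any(p < 0)) config_error("segment_proportions must be nonnegative")
  if (abs(sum(p) - 1) > 1e-9) {
    config_error("segment_proportions must sum to 1 (within 1e-9)")
  }
  cfg$segment_proportions <- p

  for (nm in c("demographics", "baseline_rates", "followup_rates")) {
    tb <- cfg[[nm]]
    if (!all(segment_levels() %in% as.character(tb$segment))) {
      config_error(paste0(nm, " must cover all six segments"))
    }
  }
  dem <- cfg$demographics
  if (any(dem$age_sd <= 0)) config_error("demographics age_sd must be positive")
  eth <- as.matrix(dem[, c("p_chinese", "p_malay", "p_indian", "p_others")])
  if (any(eth < 0)) config_error("ethnicity fractions must be nonnegative")
  cfg$demographics[, c("p_chinese", "p_malay", "p_indian", "p_others")] <-
    eth / rowSums(eth)

  for (nm in c("baseline_rates", "followup_rates")) {
    m <- as.matrix(cfg[[nm]][, encounter_kinds()])
    if (any(m < 0)) config_error(paste0(nm, " must be nonnegative"))
  }

  a <- cfg$dispersion
  if (!setequal(names(a), encounter_kinds()) || any(a < 0)) {
    config_error("dispersion must be a nonnegative vector named ED, SOC, INPATIENT")
  }
  cfg$dispersion <- a[encounter_kinds()]

  ys <- cfg$yearly_survival
  if (!setequal(names(ys), segment_levels())) {
    config_error("yearly_survival must be a list named over the six segment codes")
  }
  for (seg in segment_levels()) {
    s <- ys[[seg]]
    if (length(s) != 3 || any(s <= 0) || any(s > 1)) {
      config_error(paste0("yearly_survival[", seg, "] must be 3 values in (0, 1]"))
    }
    if (is.unsorted(rev(s))) {
      config_error(paste0("yearly_survival[", seg, "] must be nonincreasing"))
    }
  }

  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 || is.na(cfg$seed)) {
    config_error("seed must be a single integer")
  }
  cfg
}

#' @export
print.popseg_config <- function(x, ...) {
  cat("<popseg_config>\n")
  cat("  n_patients:", x$n_patients, "  seed:", x$seed, "\n")
  cat("  segment proportions:\n")
  print(round(x$segment_proportions, 4))
  invisible(x)
}

#' Read / write a generator configuration as YAML
#'
#' Round-trips a [cohort_config()] through a YAML file, mirroring the
#' configuration structure field by field.
#'
#' @param cfg a `popseg_config`.
#' @param path file path.
#' @return `write_config()` the path, invisibly; `read_config()` a validated
#'   `popseg_config`.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "popseg_config"))
  out <- list(
    n_patients = cfg$n_patients,
    seed = cfg$seed,
    segment_proportions = as.list(cfg$segment_proportions),
    dispersion = as.list(cfg$dispersion),
    yearly_survival = cfg$yearly_survival,
    demographics = lapply(split_by_segment(cfg$demographics), as.list),
    baseline_rates = lapply(split_by_segment(cfg$baseline_rates), as.list),
    followup_rates = lapply(split_by_segment(cfg$followup_rates), as.list)
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  seg_tbl <- function(x) {
    bind_rows(lapply(names(x), function(seg) {
      as_tibble(c(list(segment = seg), x[[seg]]))
    })) |> mutate(segment = as_segment(.data$segment)) |> arrange(.data$segment)
  }
  cohort_config(
    n_patients = raw$n_patients,
    segment_proportions = unlist(raw$segment_proportions),
    demographics = seg_tbl(raw$demographics),
    baseline_rates = seg_tbl(raw$baseline_rates),
    followup_rates = seg_tbl(raw$followup_rates),
    dispersion = unlist(raw$dispersion),
    yearly_survival = lapply(raw$yearly_survival, as.numeric),
    seed = raw$seed
  )
}

split_by_segment <- function(tb) {
  segs <- as.character(tb$segment)
  rows <- lapply(seq_len(nrow(tb)), function(i) {
    r <- tb[i, setdiff(names(tb), "segment")]
    as.list(r)
  })
  setNames(rows, segs)
}
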