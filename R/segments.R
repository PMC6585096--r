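#' Population segment vocabulary
#'
#' The framework partitions an adult cohort into six mutually exclusive
#' segments defined from baseline-year data. `segment_levels()` returns the
#' canonical codes in severity-ascending display order; `segment_labels()`
#' returns the human-readable names used in rendered tables.
#'
#' @return `segment_levels()`: character vector of six segment codes.
#'   `segment_labels()`: named character vector mapping code to display label.
#' @export
#' @examples
#' segment_levels()
#' segment_labels()[["COMPLEX_CHRONIC_FREQ"]]
segment_levels <- function() {
  c("MOSTLY_HEALTHY", "SERIOUS_ACUTE", "STABLE_CHRONIC",
    "COMPLEX_CHRONIC_NO_FREQ", "COMPLEX_CHRONIC_FREQ", "END_OF_LIFE")
}

#' @rdname segment_levels
#' @export
segment_labels <- function() {
  c(MOSTLY_HEALTHY          = "Mostly Healthy",
    SERIOUS_ACUTE           = "Serious Acute",
    STABLE_CHRONIC          = "Stable Chronic",
    COMPLEX_CHRONIC_NO_FREQ = "Complex Chronic without Frequent Hospital Admissions",
    COMPLEX_CHRONIC_FREQ    = "Complex Chronic with Frequent Hospital Admissions",
    END_OF_LIFE             = "End of Life")
}

#' Encounter types
#'
#' Three encounter kinds are tracked: emergency department attendances (`ED`),
#' specialist outpatient clinic attendances (`SOC`) and hospital admissions
#' (`INPATIENT`).
#'
#' @return Character vector of the three encounter kinds.
#' @export
encounter_kinds <- function() c("ED", "SOC", "INPATIENT")

#' Default chronic-condition vocabulary
#'
#' A stand-in category list of common chronic disease groups used by the
#' default segmentation rules and the synthetic generator. Real deployments
#' supply their own vocabulary mapped from local diagnosis coding.
#'
#' @return Character vector of chronic condition category identifiers.
#' @export
default_chronic_vocabulary <- function() {
  c("diabetes", "hypertension", "hyperlipidemia", "ischemic_heart_disease",
    "stroke", "copd_asthma", "chronic_kidney_disease", "heart_failure")
}

as_segment <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), segment_levels())
  if (length(bad) > 0) {
    abort(paste0("unknown segment code(s): ", paste(bad, collapse = ", ")),
          class = "popseg_error_data")
  }
  factor(x, levels = segment_levels())
}

study_dates <- function() {
  list(baseline_start = as.Date("2012-01-01"),
       baseline_end   = as.Date("2012-12-31"),
       entry          = as.Date("2013-01-01"),
       study_end      = as.Date("2015-12-31"),
       horizon_days   = 1094L)
}
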