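#' Construct per-patient survival records
#'
#' Follow-up runs from study entry (2013-01-01) to the study end
#' (2015-12-31), an administrative censoring horizon of 1094 days. A patient
#' who dies on or before the study end contributes the calendar-day
#' difference between death and entry with `event = 1`; anyone else (no death
#' recorded, or death after the study end) contributes exactly 1094 days with
#' `event = 0`. Deaths recorded on the entry date itself contribute time 0
#' with `event = 1` and are retained (count models floor their exposure to
#' one day).
#'
#' `survival_records()` is the cohort-level constructor: patients whose death
#' date precedes study entry are excluded (with a message giving the count),
#' since they never enter follow-up. `compute_survival_time()` is the
#' single-patient primitive and treats a pre-entry death as an error.
#'
#' @param patients patient tibble with `patient_id` and `death_date`.
#' @param death_date a single Date or `NA`.
#' @param entry,study_end study entry and end dates.
#' @return `survival_records()`: tibble `patient_id`, `time_days`, `event`.
#'   `compute_survival_time()`: a one-row tibble `time_days`, `event`.
#' @export
#' @examples
#' compute_survival_time(as.Date("2014-01-01")) # 365 days, event 1
#' compute_survival_time(as.Date(NA))           # 1094 days, censored
compute_survival_time <- function(death_date,
                                  entry = study_dates()$entry,
                                  study_end = study_dates()$study_end) {
  stopifnot(length(death_date) == 1)
  horizon <- as.integer(study_end - entry)
  if (!is.na(death_date) && death_date < entry) {
    abort("death_date precedes study entry: patient never enters follow-up",
          class = "popseg_error_eligibility")
  }
  if (!is.na(death_date) && death_date <= study_end) {
    tibble(time_days = as.integer(death_date - entry), event = 1L)
  } else {
    tibble(time_days = horizon, event = 0L)
  }
}

#' @rdname compute_survival_time
#' @export
survival_records <- function(patients,
                             entry = study_dates()$entry,
                             study_end = study_dates()$study_end) {
  horizon <- as.integer(study_end - entry)
  pre <- !is.na(patients$death_date) & patients$death_date < entry
  if (any(pre)) {
    message(sum(pre), " patient(s) died before study entry; excluded from follow-up")
    patients <- patients[!pre, ]
  }
  died <- !is.na(patients$death_date) & patients$death_date <= study_end
  tibble(
    patient_id = patients$patient_id,
    time_days = ifelse(died, as.integer(patients$death_date - entry), horizon),
    event = as.integer(died)
  )
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator S(t) = prod over event times t_i <= t of
#' (1 - d_i / n_i), with tied deaths aggregated and patients censored at an
#' event time still counted in that time's risk set. Estimation is delegated
#' to [survival::survfit()].
#'
#' @param records survival tibble (`time_days`, `event`), nonempty.
#' @return An object of class `popseg_km`: the step curve as a tibble
#'   (`time`, `n_risk`, `n_event`, `n_censor`, `survival`) plus the sample
#'   size. Use [survival_at()] to evaluate it and [tidy()] to extract the
#'   curve.
#' @export
#' @examples
#' rec <- tibble::tibble(time_days = c(2, 4, 4, 6), event = c(1, 1, 1, 0))
#' km <- km_estimate(rec)
#' survival_at(km, 4) # 0.25
km_estimate <- function(records) {
  if (nrow(records) == 0) {
    abort("cannot estimate a survival curve from zero records",
          class = "popseg_error_estimation")
  }
  fit <- survival::survfit(
    survival::Surv(time_days, event) ~ 1,
    data = records, conf.type = "none")
  curve <- tibble(time = fit$time, n_risk = fit$n.risk,
                  n_event = fit$n.event, n_censor = fit$n.censor,
                  survival = fit$surv)
  structure(list(curve = curve, n = nrow(records)), class = "popseg_km")
}

#' Per-segment Kaplan-Meier curves
#'
#' @param records survival tibble.
#' @param segments tibble (`patient_id`, `segment`) covering all records.
#' @return Tibble of stacked step curves with a leading `segment` column.
#' @export
km_by_segment <- function(records, segments) {
  joined <- records |> left_join(segments, by = "patient_id")
  if (anyNA(joined$segment)) data_error("unsegmented patient in survival records")
  joined |>
    group_by(.data$segment) |>
    dplyr::group_modify(~ tidy(km_estimate(.x))) |>
    ungroup()
}

#' @export
print.popseg_km <- function(x, ...) {
  cat("<popseg_km> Kaplan-Meier curve, n =", x$n, "\n")
  cat("  events:", sum(x$curve$n_event), " distinct times:", nrow(x$curve), "\n")
  invisible(x)
}

#' @method tidy popseg_km
#' @export
tidy.popseg_km <- function(x, ...) x$curve

#' @method glance popseg_km
#' @export
glance.popseg_km <- function(x, ...) {
  tibble(n = x$n, n_events = sum(x$curve$n_event),
         s_365 = survival_at(x, 365), s_730 = survival_at(x, 730),
         s_1094 = survival_at(x, 1094))
}

#' Evaluate a Kaplan-Meier curve
#'
#' Right-continuous step-function evaluation: S(t) is the survival after the
#' last event time at or before `t`, and 1 before the first.
#'
#' @param km a `popseg_km` object.
#' @param t day (vectorised), `>= 0`.
#' @return Numeric survival probabilities in `[0, 1]`.
#' @export
survival_at <- function(km, t) {
  stopifnot(inherits(km, "popseg_km"), all(t >= 0))
  vapply(t, function(ti) {
    below <- km$curve$time <= ti
    if (!any(below)) 1 else km$curve$survival[max(which(below))]
  }, numeric(1))
}

#' K-group log-rank test
#'
#' Standard log-rank chi-square over pooled risk sets comparing observed and
#' expected event counts by group, with K - 1 degrees of freedom; delegated
#' to [survival::survdiff()].
#'
#' @param records survival tibble with `patient_id`.
#' @param labels tibble (`patient_id`, group column named `segment` or
#'   `group`) assigning every record to one of K >= 2 groups.
#' @return An object of class `popseg_logrank` with `statistic`, `df`,
#'   `p_value`, and per-group observed/expected counts.
#' @export
log_rank_test <- function(records, labels) {
  gcol <- intersect(c("segment", "group"), names(labels))[1]
  if (is.na(gcol)) config_error("labels must have a 'segment' or 'group' column")
  joined <- records |> left_join(labels, by = "patient_id")
  if (anyNA(joined[[gcol]])) data_error("unlabeled patient in log-rank input")
  joined$.group <- factor(as.character(joined[[gcol]]))
  counts <- table(joined$.group)
  if (length(counts) < 2) config_error("log-rank test needs at least 2 groups")
  if (any(counts == 0)) config_error("log-rank group with zero members")
  fit <- survival::survdiff(survival::Surv(time_days, event) ~ .group,
                            data = joined)
  df <- length(counts) - 1L
  structure(
    list(statistic = unname(fit$chisq), df = df,
         p_value = pchisq(fit$chisq, df, lower.tail = FALSE),
         observed = fit$obs, expected = fit$exp,
         groups = names(counts)),
    class = "popseg_logrank")
}

#' @export
print.popseg_logrank <- function(x, ...) {
  cat("<popseg_logrank> chi-square =", format(x$statistic, digits = 4),
      " df =", x$df, " p =", format.pval(x$p_value, digits = 3), "\n")
  invisible(x)
}

#' @method tidy popseg_logrank
#' @export
tidy.popseg_logrank <- function(x, ...) {
  tibble(group = x$groups, observed = as.numeric(x$observed),
         expected = as.numeric(x$expected))
}

#' @method glance popseg_logrank
#' @export
glance.popseg_logrank <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p_value = x$p_value)
}
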