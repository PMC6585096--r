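# Shared fixtures and independent oracles.

srec <- function(time, event, ids = NULL) {
  tibble::tibble(
    patient_id = if (is.null(ids)) sprintf("p%03d", seq_along(time)) else ids,
    time_days = time, event = event)
}

# One archetype patient per segment, with the 2012 encounters that force the
# default rules to produce that label.
archetype_cohort <- function() {
  d <- function(x) as.Date(x)
  patients <- tibble::tibble(
    patient_id = c("mh", "sa", "sc", "ccnf", "ccf", "eol"),
    age_2012 = c(30L, 55L, 40L, 62L, 70L, 58L),
    gender = c("female", "male", "female", "male", "male", "female"),
    ethnicity = c("Chinese", "Malay", "Indian", "Chinese", "Chinese", "Others"),
    death_date = as.Date(rep(NA_character_, 6)),
    chronic_conditions = c("", "", "diabetes",
                           "diabetes;hypertension",
                           "diabetes;heart_failure", "chronic_kidney_disease"),
    serious_acute = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
    end_of_life_condition = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE))
  encounters <- dplyr::bind_rows(
    tibble::tibble(patient_id = "mh", date = d("2012-05-01"), kind = "SOC"),
    tibble::tibble(patient_id = "sa", date = d("2012-06-01"), kind = "ED"),
    tibble::tibble(patient_id = "sc", date = d("2012-04-01"), kind = "SOC"),
    tibble::tibble(patient_id = "ccnf",
                   date = d(c("2012-02-01", "2012-07-01")),
                   kind = c("INPATIENT", "INPATIENT")),
    tibble::tibble(patient_id = "ccf",
                   date = d(c("2012-01-10", "2012-05-10", "2012-09-10")),
                   kind = "INPATIENT"),
    tibble::tibble(patient_id = "eol", date = d("2012-03-15"), kind = "SOC"))
  list(patients = patients, encounters = encounters,
       truth = c(mh = "MOSTLY_HEALTHY", sa = "SERIOUS_ACUTE",
                 sc = "STABLE_CHRONIC", ccnf = "COMPLEX_CHRONIC_NO_FREQ",
                 ccf = "COMPLEX_CHRONIC_FREQ", eol = "END_OF_LIFE"))
}

# Brute-force product-limit estimator over explicit risk sets.
km_oracle <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  surv <- numeric(length(ts))
  s <- 1
  for (i in seq_along(ts)) {
    n_i <- sum(time >= ts[i])
    d_i <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d_i / n_i)
    surv[i] <- s
  }
  list(time = ts, surv = surv)
}

km_oracle_at <- function(time, event, t) {
  o <- km_oracle(time, event)
  keep <- o$time <= t
  if (!any(keep)) 1 else o$surv[max(which(keep))]
}

# Brute-force 2-group log-rank chi-square over pooled risk sets.
logrank_oracle_2g <- function(time, event, group) {
  g <- unique(group)
  stopifnot(length(g) == 2)
  ts <- sort(unique(time[event == 1]))
  O1 <- 0; E1 <- 0; V <- 0
  for (t in ts) {
    n_t <- sum(time >= t)
    n_1t <- sum(time >= t & group == g[1])
    d_t <- sum(time == t & event == 1)
    d_1t <- sum(time == t & event == 1 & group == g[1])
    O1 <- O1 + d_1t
    E1 <- E1 + d_t * n_1t / n_t
    if (n_t > 1) {
      V <- V + d_t * (n_1t / n_t) * (1 - n_1t / n_t) * (n_t - d_t) / (n_t - 1)
    }
  }
  (O1 - E1)^2 / V
}

table3_multipliers <- function(outcome) {
  irr <- reference_irr()
  v <- irr$irr[irr$outcome == outcome]
  stats::setNames(v, as.character(irr$segment[irr$outcome == outcome]))
}
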