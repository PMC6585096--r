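#' @section Seeding:
#' One master integer seed drives the whole generator. Each generation stage
#' (segment assignment, ages, gender, ethnicity, chronic conditions, each
#' baseline outcome, death times, each follow-up outcome, encounter dates)
#' draws from its own sub-stream, seeded by a deterministic hash of the master
#' seed and the stage name. Within a stage, draws are made in patient order,
#' so enlarging the cohort never perturbs the draws of earlier patients.
#' @name popseg-seeding
#' @keywords internal
NULL

stage_seed <- function(seed, stage) {
  codes <- utf8ToInt(stage)
  h <- 0
  for (c in codes) h <- (h * 31 + c) %% 2147483629
  as.integer((abs(as.numeric(seed)) + h) %% 2147483629)
}

with_stage_seed <- function(seed, stage, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(stage_seed(seed, stage))
  expr
}

data_error <- function(msg) abort(msg, class = "popseg_error_data")

#' Generate a synthetic baseline cohort
#'
#' Draws a cohort of synthetic patients whose baseline-2012 features are
#' consistent, by construction, with their assigned population segment:
#' a patient assigned to Complex Chronic with Frequent Hospital Admissions
#' receives at least three 2012 inpatient admissions, every other patient at
#' most two; chronic-condition counts and the serious-acute / end-of-life
#' flags are set so that [segment_cohort()] with [default_rules()] reproduces
#' the assignment exactly (the round-trip property). Every patient receives at
#' least one 2012 encounter, so the whole cohort passes [filter_eligible()].
#'
#' @param config a [cohort_config()].
#' @return A list with elements `patients` (tibble: `patient_id`, `age_2012`,
#'   `gender`, `ethnicity`, `death_date` (all `NA` until
#'   [sample_followup_outcomes()] is applied), `chronic_conditions`
#'   (semicolon-joined category ids), `serious_acute`,
#'   `end_of_life_condition`), `encounters` (tibble: `patient_id`, `date`,
#'   `kind`, all dated in 2012) and `true_segments` (tibble: `patient_id`,
#'   `segment`).
#' @seealso [sample_followup_outcomes()], [segment_cohort()]
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 200, seed = 42))
#' dplyr::count(cohort$true_segments, segment)
generate_cohort <- function(config) {
  config <- validate_config(config)
  n <- config$n_patients
  dates <- study_dates()

  if (n == 0L) {
    return(list(
      patients = empty_patients(),
      encounters = empty_encounters(),
      true_segments = tibble(patient_id = character(),
                             segment = as_segment(character()))
    ))
  }

  seed <- config$seed
  segs <- with_stage_seed(seed, "segments", {
    sample(segment_levels(), n, replace = TRUE,
           prob = config$segment_proportions)
  })
  seg_idx <- match(segs, segment_levels())
  dem <- config$demographics |> arrange(.data$segment)

  ages <- with_stage_seed(seed, "ages", {
    a <- rnorm(n, mean = dem$age_mean[seg_idx], sd = dem$age_sd[seg_idx])
    as.integer(round(pmin(pmax(a, 21), 100)))
  })
  gender <- with_stage_seed(seed, "gender", {
    ifelse(runif(n) < dem$p_male[seg_idx], "male", "female")
  })
  ethnicity <- with_stage_seed(seed, "ethnicity", {
    eth <- as.matrix(dem[, c("p_chinese", "p_malay", "p_indian", "p_others")])
    cum <- t(apply(eth, 1, cumsum))
    u <- runif(n)
    lvl <- c("Chinese", "Malay", "Indian", "Others")
    lvl[1L + (u > cum[seg_idx, 1]) + (u > cum[seg_idx, 2]) + (u > cum[seg_idx, 3])]
  })

  # Chronic-condition counts are forced to match each segment's definition:
  # none for Mostly Healthy / Serious Acute, exactly one for Stable Chronic,
  # two or more for the Complex Chronic segments; End of Life patients carry
  # one to four (their label is determined by the end-of-life flag alone).
  # every sub-stream draws exactly n values so that enlarging the cohort
  # leaves earlier patients' conditions untouched
  k <- integer(n)
  k[segs == "STABLE_CHRONIC"] <- 1L
  cc <- segs %in% c("COMPLEX_CHRONIC_NO_FREQ", "COMPLEX_CHRONIC_FREQ")
  k[cc] <- 2L + with_stage_seed(seed, "chronic_extra_cc",
                                rbinom(n, 3L, 0.4))[cc]
  eol <- segs == "END_OF_LIFE"
  k[eol] <- 1L + with_stage_seed(seed, "chronic_extra_eol",
                                 rbinom(n, 3L, 0.3))[eol]
  vocab <- default_chronic_vocabulary()
  keys <- do.call(cbind, lapply(seq_along(vocab), function(j) {
    with_stage_seed(seed, paste0("chronic_key_", j), runif(n))
  }))
  chronic <- vapply(seq_len(n), function(i) {
    if (k[i] == 0L) "" else {
      paste(sort(vocab[order(keys[i, ])[seq_len(k[i])]]), collapse = ";")
    }
  }, character(1))

  base <- config$baseline_rates |> arrange(.data$segment)
  counts <- list()
  counts$ED <- with_stage_seed(seed, "baseline_ED",
                               rpois(n, base$ED[seg_idx]))
  counts$SOC <- with_stage_seed(seed, "baseline_SOC",
                                rpois(n, base$SOC[seg_idx]))
  counts$INPATIENT <- local({
    adm <- with_stage_seed(seed, "baseline_INPATIENT",
                           pmin(rpois(n, base$INPATIENT[seg_idx]), 2L))
    extra <- with_stage_seed(seed, "baseline_INPATIENT_extra",
                             rpois(n, pmax(base$INPATIENT[seg_idx] - 3, 0)))
    freq <- segs == "COMPLEX_CHRONIC_FREQ"
    adm[freq] <- 3L + extra[freq]
    adm
  })
  # guarantee eligibility: every patient has >= 1 encounter in 2012
  none <- counts$ED + counts$SOC + counts$INPATIENT == 0L
  counts$SOC[none] <- 1L

  ids <- sprintf("P%07d", seq_len(n))
  baseline_days <- as.integer(dates$baseline_end - dates$baseline_start) + 1L
  enc <- purrr::map(encounter_kinds(), function(kind) {
    k <- counts[[kind]]
    total <- sum(k)
    offsets <- with_stage_seed(seed, paste0("baseline_dates_", kind), {
      floor(runif(total) * baseline_days)
    })
    tibble(patient_id = rep(ids, times = k),
           date = dates$baseline_start + offsets,
           kind = kind)
  }) |> bind_rows()

  list(
    patients = tibble(
      patient_id = ids,
      age_2012 = ages,
      gender = gender,
      ethnicity = ethnicity,
      death_date = as.Date(rep(NA_character_, n)),
      chronic_conditions = chronic,
      serious_acute = segs == "SERIOUS_ACUTE",
      end_of_life_condition = segs == "END_OF_LIFE"
    ),
    encounters = enc,
    true_segments = tibble(patient_id = ids, segment = as_segment(segs))
  )
}

empty_patients <- function() {
  tibble(patient_id = character(), age_2012 = integer(),
         gender = character(), ethnicity = character(),
         death_date = as.Date(character()),
         chronic_conditions = character(),
         serious_acute = logical(), end_of_life_condition = logical())
}

empty_encounters <- function() {
  tibble(patient_id = character(), date = as.Date(character()),
         kind = character())
}

# Piecewise-exponential death-time draw with knots at days 365/730/1094;
# hazards solved from the configured yearly survival. Returns days from entry
# (2013-01-01); NA_real_ for patients surviving past day 1094.
draw_death_days <- function(u, s) {
  s1 <- s[1]; s2 <- s[2]; s3 <- s[3]
  l1 <- -log(s1) / 365
  l2 <- -log(s2 / s1) / 365
  l3 <- -log(s3 / s2) / 364
  t <- rep(NA_real_, length(u))
  in1 <- u > s1
  if (l1 > 0) t[in1] <- -log(u[in1]) / l1
  in2 <- !in1 & u > s2
  if (l2 > 0) t[in2] <- 365 + (log(s1) - log(u[in2])) / l2
  in3 <- !in1 & !in2 & u > s3
  if (l3 > 0) t[in3] <- 730 + (log(s2) - log(u[in3])) / l3
  floor(pmin(t, 1094))
}

#' Simulate follow-up mortality and utilization
#'
#' Applies the 2013-2015 follow-up model to a baseline cohort. Death times are
#' drawn from a per-segment piecewise-exponential model with knots at the
#' follow-up year boundaries (days 365, 730 and 1094 after entry on
#' 2013-01-01), with hazards solved so that survival at each knot equals the
#' configured yearly survival. Encounter counts per outcome are drawn from an
#' NB2 distribution (variance mu + alpha * mu^2) whose mean is the segment's
#' per-day rate times the patient's realized survived days, so no encounters
#' ever fall after death; outcomes are drawn independently given segment.
#'
#' @param patients patient tibble from [generate_cohort()].
#' @param true_segments tibble (`patient_id`, `segment`) covering every patient.
#' @param config the [cohort_config()] used for generation.
#' @return A list with `patients` (death dates filled in) and `encounters`
#'   (tibble of 2013-2015 encounters).
#' @export
sample_followup_outcomes <- function(patients, true_segments, config) {
  config <- validate_config(config)
  dates <- study_dates()
  n <- nrow(patients)
  if (n == 0L) {
    return(list(patients = patients, encounters = empty_encounters()))
  }
  seg <- true_segments$segment[match(patients$patient_id,
                                     true_segments$patient_id)]
  if (anyNA(seg)) {
    data_error(paste0("no segment assigned for patient(s): ",
                      paste(utils::head(patients$patient_id[is.na(seg)], 5),
                            collapse = ", ")))
  }
  seed <- config$seed
  seg <- as.character(seg)

  death_day <- with_stage_seed(seed, "death_times", {
    u <- runif(n)
    out <- rep(NA_real_, n)
    for (s in unique(seg)) {
      idx <- seg == s
      out[idx] <- draw_death_days(u[idx], config$yearly_survival[[s]])
    }
    out
  })
  patients$death_date <- dates$entry + death_day  # NA stays NA
  survived_days <- ifelse(is.na(death_day), dates$horizon_days, death_day)

  rates <- config$followup_rates |> arrange(.data$segment)
  seg_idx <- match(seg, segment_levels())
  enc <- purrr::map(encounter_kinds(), function(kind) {
    mu <- rates[[kind]][seg_idx] * survived_days
    alpha <- config$dispersion[[kind]]
    k <- with_stage_seed(seed, paste0("followup_", kind), {
      if (alpha == 0) rpois(n, mu) else rnbinom(n, size = 1 / alpha, mu = mu)
    })
    k[mu == 0] <- 0L
    total <- sum(k)
    span <- rep(pmax(survived_days, 1), times = k)
    offsets <- with_stage_seed(seed, paste0("followup_dates_", kind), {
      floor(runif(total) * span)
    })
    tibble(patient_id = rep(patients$patient_id, times = k),
           date = dates$entry + offsets,
           kind = kind)
  }) |> bind_rows()

  list(patients = patients, encounters = enc)
}

#' Simulate a balanced cohort for rate-ratio recovery
#'
#' Draws a six-segment cohort designed for parameter-recovery studies of the
#' negative binomial utilization model: segment sizes are balanced (n/6 each),
#' demographic covariates are drawn independently of segment (so they carry no
#' true effect), every patient contributes the full 1094-day exposure, and
#' counts follow NB2 with mean `baseline_mean * multiplier[segment]`. The
#' estimable truth is therefore exactly the supplied multiplier vector.
#'
#' @param n total cohort size (split as evenly as possible across segments).
#' @param multipliers named numeric vector over [segment_levels()] of true
#'   rate multipliers relative to `MOSTLY_HEALTHY` (whose entry must be 1).
#' @param baseline_mean expected count for the reference segment over the full
#'   exposure window.
#' @param dispersion NB2 alpha for the simulated counts.
#' @param exposure_days exposure (offset) per patient, default the 1094-day
#'   follow-up horizon.
#' @param seed integer seed.
#' @return Tibble with `patient_id`, `segment`, `age`, `gender`, `ethnicity`,
#'   `count`, `exposure_days`.
#' @export
#' @examples
#' sim <- simulate_irr_cohort(600, seed = 1)
#' dplyr::count(sim, segment)
simulate_irr_cohort <- function(n,
                                multipliers = setNames(rep(1, 6), segment_levels()),
                                baseline_mean = 1,
                                dispersion = 1,
                                exposure_days = 1094,
                                seed = 1L) {
  seed <- as.integer(seed)  # force now: stage sub-streams save/restore the
                            # global RNG state, so a lazily drawn seed would
                            # otherwise be un-drawn on exit
  stopifnot(setequal(names(multipliers), segment_levels()),
            multipliers[["MOSTLY_HEALTHY"]] == 1, all(multipliers > 0),
            dispersion >= 0, baseline_mean > 0, n >= 6)
  multipliers <- multipliers[segment_levels()]
  per <- rep(n %/% 6L, 6L)
  per[seq_len(n %% 6L)] <- per[seq_len(n %% 6L)] + 1L
  seg <- rep(segment_levels(), times = per)

  age <- with_stage_seed(seed, "irr_age",
                         pmin(pmax(rnorm(n, 50, 17), 21), 100))
  gender <- with_stage_seed(seed, "irr_gender",
                            ifelse(runif(n) < 0.42, "male", "female"))
  ethnicity <- with_stage_seed(seed, "irr_ethnicity", {
    sample(c("Chinese", "Malay", "Indian", "Others"), n, replace = TRUE,
           prob = c(0.707, 0.108, 0.086, 0.099))
  })
  mu <- baseline_mean * multipliers[seg]
  cnt <- with_stage_seed(seed, "irr_counts", {
    if (dispersion == 0) rpois(n, mu)
    else rnbinom(n, size = 1 / dispersion, mu = mu)
  })
  tibble(patient_id = sprintf("S%07d", seq_len(n)),
         segment = as_segment(seg),
         age = age, gender = gender, ethnicity = ethnicity,
         count = as.integer(cnt),
         exposure_days = exposure_days)
}
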