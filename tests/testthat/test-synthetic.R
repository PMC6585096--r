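test_that("segment shares at n=100,000 match the configured mixture", {
  cfg <- cohort_config(n_patients = 100000, seed = 1)
  co <- generate_cohort(cfg)
  shares <- table(factor(co$true_segments$segment, segment_levels())) / 100000
  target <- c(0.588, 0.245, 0.053, 0.107, 0.005, 0.002)
  expect_true(all(abs(as.numeric(shares) - target) <= 0.005))

  # baseline encounters respect the segment-defining admission rule
  seg <- co$true_segments
  adm <- co$encounters |>
    dplyr::filter(kind == "INPATIENT") |>
    dplyr::count(patient_id)
  n_adm <- adm$n[match(seg$patient_id, adm$patient_id)]
  n_adm[is.na(n_adm)] <- 0L
  freq <- as.character(seg$segment) == "COMPLEX_CHRONIC_FREQ"
  expect_true(all(n_adm[freq] >= 3))
  expect_true(all(n_adm[!freq] <= 2))
  expect_true(all(co$encounters$date >= as.Date("2012-01-01") &
                    co$encounters$date <= as.Date("2012-12-31")))
})

test_that("degenerate inputs: empty cohort and single-segment mixture", {
  co0 <- generate_cohort(cohort_config(n_patients = 0, seed = 3))
  expect_equal(nrow(co0$patients), 0)
  expect_equal(nrow(co0$encounters), 0)
  expect_equal(nrow(co0$true_segments), 0)

  p <- setNames(c(1, 0, 0, 0, 0, 0), segment_levels())
  co1 <- generate_cohort(cohort_config(100, segment_proportions = p, seed = 2))
  expect_equal(nrow(co1$patients), 100)
  seg <- segment_cohort(co1$patients, co1$encounters)
  expect_true(all(as.character(seg$segment) == "MOSTLY_HEALTHY"))
})

test_that("generator-classifier round trip holds exactly across seeds", {
  for (s in c(4, 19, 820)) {
    co <- generate_cohort(cohort_config(n_patients = 3000, seed = s))
    seg <- segment_cohort(co$patients, co$encounters)
    expect_identical(as.character(seg$segment),
                     as.character(co$true_segments$segment))
  }
})

test_that("follow-up survival honours the configured yearly survival", {
  # no-mortality limit
  ys <- reference_yearly_survival()
  ys <- lapply(ys, function(x) c(1, 1, 1))
  cfg <- cohort_config(1000, yearly_survival = ys, seed = 5)
  co <- generate_cohort(cfg)
  fu <- sample_followup_outcomes(co$patients, co$true_segments, cfg)
  expect_true(all(is.na(fu$patients$death_date)))
  sr <- survival_records(fu$patients)
  expect_true(all(sr$time_days == 1094L & sr$event == 0L))

  # End of Life segment alone, year-3 survival 0.582
  p <- setNames(c(0, 0, 0, 0, 0, 1), segment_levels())
  cfg2 <- cohort_config(5000, segment_proportions = p, seed = 6)
  co2 <- generate_cohort(cfg2)
  fu2 <- sample_followup_outcomes(co2$patients, co2$true_segments, cfg2)
  sr2 <- survival_records(fu2$patients)
  alive <- mean(sr2$event == 0)
  expect_lt(abs(alive - 0.582), 0.02)
  # deaths never beyond the horizon; no encounter after death
  dd <- fu2$patients$death_date
  expect_true(all(is.na(dd) | dd <= as.Date("2015-12-31")))
  joined <- fu2$encounters |>
    dplyr::left_join(dplyr::select(fu2$patients, patient_id, death_date),
                     by = "patient_id") |>
    dplyr::filter(!is.na(death_date))
  expect_true(all(joined$date <= joined$death_date))
})

test_that("zero follow-up rates produce zero follow-up encounters", {
  fr <- default_followup_rates()
  fr$ED <- fr$SOC <- fr$INPATIENT <- 0
  cfg <- cohort_config(300, followup_rates = fr, seed = 7)
  co <- generate_cohort(cfg)
  fu <- sample_followup_outcomes(co$patients, co$true_segments, cfg)
  expect_equal(nrow(fu$encounters), 0)
})

test_that("missing segment assignment is a data-integrity error", {
  cfg <- cohort_config(20, seed = 8)
  co <- generate_cohort(cfg)
  expect_error(
    sample_followup_outcomes(co$patients, co$true_segments[-1, ], cfg),
    class = "popseg_error_data")
})

test_that("counts are equidispersed in the alpha -> 0 limit", {
  p <- setNames(c(1, 0, 0, 0, 0, 0), segment_levels())
  ys <- lapply(reference_yearly_survival(), function(x) c(1, 1, 1))
  cfg <- cohort_config(5000, segment_proportions = p, yearly_survival = ys,
                       dispersion = c(ED = 0, SOC = 0, INPATIENT = 0),
                       seed = 9)
  co <- generate_cohort(cfg)
  fu <- sample_followup_outcomes(co$patients, co$true_segments, cfg)
  counts <- aggregate_counts(fu$encounters, co$patients$patient_id)
  ratio <- stats::var(counts$SOC) / mean(counts$SOC)
  expect_lt(abs(ratio - 1), 3 * sqrt(2 / 5000) + 0.02)
})

test_that("generated rates calibrate to the configured rates at n=100,000", {
  cfg <- cohort_config(100000, seed = 1)
  co <- generate_cohort(cfg)
  fu <- sample_followup_outcomes(co$patients, co$true_segments, cfg)
  sr <- survival_records(fu$patients)
  counts <- aggregate_counts(fu$encounters, sr$patient_id)
  util <- summarize_utilization(counts, sr, co$true_segments)
  rates <- cfg$followup_rates |>
    tidyr::pivot_longer(dplyr::all_of(encounter_kinds()),
                        names_to = "outcome", values_to = "rate_per_day") |>
    dplyr::mutate(target = rate_per_day * 1000)
  chk <- util |>
    dplyr::filter(segment != "All") |>
    dplyr::left_join(rates, by = c("segment", "outcome"))
  # analytic SE of the empirical rate under NB2 sampling; the 5% band applies
  # where it is wide relative to that noise, a 4-SE band otherwise
  alpha <- cfg$dispersion[chk$outcome]
  mu_bar <- chk$target / 1000 * chk$patient_days / chk$n_patients
  se_rel <- sqrt(mu_bar + alpha * mu_bar^2) / mu_bar / sqrt(chk$n_patients)
  strict <- 0.05 >= 3 * se_rel
  tol <- ifelse(strict, 0.05, 4 * se_rel)
  rel_err <- abs(chk$rate_per_1000_days - chk$target) / chk$target
  expect_true(all(rel_err <= tol))
  expect_true(any(strict)) # the 5% band is actually exercised
})

test_that("same seed gives byte-identical files, different seeds differ", {
  cfg <- cohort_config(400, seed = 11)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  d3 <- withr::local_tempdir()
  co1 <- generate_cohort(cfg)
  fu1 <- sample_followup_outcomes(co1$patients, co1$true_segments, cfg)
  write_cohort(fu1$patients, dplyr::bind_rows(co1$encounters, fu1$encounters), d1)
  co2 <- generate_cohort(cfg)
  fu2 <- sample_followup_outcomes(co2$patients, co2$true_segments, cfg)
  write_cohort(fu2$patients, dplyr::bind_rows(co2$encounters, fu2$encounters), d2)
  for (f in c("patients.csv", "encounters.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  cfg3 <- cohort_config(400, seed = 12)
  co3 <- generate_cohort(cfg3)
  write_cohort(co3$patients, co3$encounters, d3)
  expect_false(identical(readLines(file.path(d1, "encounters.csv")),
                         readLines(file.path(d3, "encounters.csv"))))
})

test_that("enlarging the cohort preserves earlier patients' draws", {
  cfg_small <- cohort_config(200, seed = 13)
  cfg_big <- cohort_config(300, seed = 13)
  a <- generate_cohort(cfg_small)$patients
  b <- generate_cohort(cfg_big)$patients[1:200, ]
  expect_equal(as.data.frame(a), as.data.frame(b))
})
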