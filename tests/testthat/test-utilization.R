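test_that("follow-up counts respect the window and match a brute-force filter", {
  enc <- tibble::tibble(
    patient_id = c("a", "a", "a", "b", "b", "c"),
    date = as.Date(c("2013-02-01", "2013-07-01", "2016-01-05",
                     "2014-03-01", "2012-06-01", "2015-12-31")),
    kind = c("ED", "ED", "ED", "SOC", "SOC", "INPATIENT"))
  counts <- aggregate_counts(enc, c("a", "b", "c", "d"))
  expect_equal(counts$ED, c(2L, 0L, 0L, 0L))
  expect_equal(counts$SOC, c(0L, 1L, 0L, 0L))
  expect_equal(counts$INPATIENT, c(0L, 0L, 1L, 0L))

  w <- as.Date(c("2013-01-01", "2015-12-31"))
  for (i in seq_len(nrow(counts))) {
    for (k in encounter_kinds()) {
      oracle <- sum(enc$patient_id == counts$patient_id[i] & enc$kind == k &
                      enc$date >= w[1] & enc$date <= w[2])
      expect_equal(counts[[k]][i], oracle)
    }
  }
})

test_that("utilization summary conserves totals and reproduces printed rates", {
  cfg <- cohort_config(1500, seed = 61)
  co <- generate_cohort(cfg)
  fu <- sample_followup_outcomes(co$patients, co$true_segments, cfg)
  sr <- survival_records(fu$patients)
  counts <- aggregate_counts(fu$encounters, sr$patient_id)
  util <- summarize_utilization(counts, sr, co$true_segments)
  for (k in encounter_kinds()) {
    seg_rows <- util |> dplyr::filter(outcome == k, segment != "All")
    all_row <- util |> dplyr::filter(outcome == k, segment == "All")
    expect_equal(sum(seg_rows$total_count), all_row$total_count)
    expect_equal(sum(seg_rows$patient_days), all_row$patient_days)
  }
  expect_equal(util$rate_per_1000_days,
               util$total_count / util$patient_days * 1000)

  # zero events with positive days is a zero rate, not an error
  z <- summarize_utilization(
    tibble::tibble(patient_id = "a", ED = 0L, SOC = 0L, INPATIENT = 0L),
    srec(1094L, 0L, "a"),
    tibble::tibble(patient_id = "a", segment = "MOSTLY_HEALTHY"))
  expect_true(all(z$rate_per_1000_days == 0))
})

test_that("bivariate tests reproduce hand chi-square and behave under the null", {
  d <- tibble::tibble(segment = rep(c("s1", "s2"), each = 30),
                      x = c(rep(c("u", "v"), c(10, 20)),
                            rep(c("u", "v"), c(20, 10))))
  res <- bivariate_test(d, "x")
  expect_equal(res$statistic, 20 / 3, tolerance = 1e-12) # sum (O-E)^2/E, E = 15
  expect_equal(res$df, 1)

  # identical distributions: statistic 0, p = 1
  d0 <- tibble::tibble(segment = rep(c("s1", "s2"), each = 20),
                       x = rep(c("u", "v"), 20))
  r0 <- bivariate_test(d0, "x")
  expect_equal(r0$statistic, 0, tolerance = 1e-12)
  expect_equal(r0$p_value, 1, tolerance = 1e-12)

  # degenerate table
  dd <- tibble::tibble(segment = rep(c("s1", "s2"), each = 5), x = "u")
  expect_error(bivariate_test(dd, "x"), class = "popseg_error_degenerate")

  # ANOVA type-I error calibration under the null
  set.seed(62)
  rej <- mean(replicate(1000, {
    dn <- tibble::tibble(segment = rep(c("a", "b", "c"), each = 30),
                         y = rnorm(90))
    bivariate_test(dn, "y")$p_value < 0.05
  }))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("intercept-only NB fit recovers the sample mean", {
  d <- tibble::tibble(segment = "MOSTLY_HEALTHY", count = rep(3L, 40),
                      exposure_days = 1)
  for (disp in c(0, 1)) {
    f <- fit_nb_regression(d, "count", covariates = NULL, dispersion = disp)
    expect_equal(exp(f$coefficients$estimate[1]), 3, tolerance = 1e-8)
  }
})

test_that("a two-group Poisson rate ratio of 2 is recovered", {
  set.seed(63)
  d <- tibble::tibble(
    segment = rep(c("MOSTLY_HEALTHY", "SERIOUS_ACUTE"), each = 2500),
    count = c(rpois(2500, 2), rpois(2500, 4)),
    exposure_days = 1)
  f <- fit_nb_regression(d, "count", covariates = NULL)
  irr <- f$irr$irr[f$irr$segment == "SERIOUS_ACUTE"]
  expect_gte(irr, 1.9)
  expect_lte(irr, 2.1)
  expect_true(f$converged)
  ci <- f$irr |> dplyr::filter(segment == "SERIOUS_ACUTE")
  expect_lte(ci$ci_low, irr)
  expect_gte(ci$ci_high, irr)
})

test_that("NB fit with dispersion fixed at ~0 reproduces the Poisson MLE", {
  set.seed(64)
  sim <- simulate_irr_cohort(3000, table3_multipliers("ED"),
                             baseline_mean = 2, dispersion = 0, seed = 64)
  f_nb <- fit_nb_regression(sim, "count", dispersion = 1e-8)
  f_pois <- fit_nb_regression(sim, "count", dispersion = 0)
  expect_equal(f_nb$coefficients$estimate, f_pois$coefficients$estimate,
               tolerance = 1e-6)
})

test_that("exposure offsets convert counts to rates (doubling invariance)", {
  mult <- table3_multipliers("INPATIENT")
  s1 <- simulate_irr_cohort(12000, mult, baseline_mean = 1,
                            dispersion = 0.5, exposure_days = 1094, seed = 65)
  s2 <- simulate_irr_cohort(12000, mult, baseline_mean = 2,
                            dispersion = 0.5, exposure_days = 2188, seed = 66)
  f1 <- fit_nb_regression(s1, "count", covariates = NULL)
  f2 <- fit_nb_regression(s2, "count", covariates = NULL)
  i1 <- f1$irr$irr[-1]; i2 <- f2$irr$irr[-1]
  expect_true(all(abs(log(i2) - log(i1)) < 0.12))
  expect_true(all(abs(log(i1) - log(mult[-1])) < 0.12))
})

test_that("rank deficiency and invalid exposure are model errors", {
  d <- tibble::tibble(segment = rep(c("MOSTLY_HEALTHY", "SERIOUS_ACUTE"), 20),
                      count = rpois(40, 2), exposure_days = 1,
                      z = 1)
  expect_error(fit_nb_regression(d, "count", covariates = "z"),
               class = "popseg_error_model")
  d2 <- d |> dplyr::mutate(exposure_days = 0, count = 1L)
  expect_error(fit_nb_regression(d2, "count", covariates = NULL),
               class = "popseg_error_model")
  expect_error(fit_nb_regression(dplyr::mutate(d, segment = "SERIOUS_ACUTE"),
                                 "count", covariates = NULL),
               class = "popseg_error_model")
})

test_that("pairwise segment tests: identity, oracle limits and type-I error", {
  set.seed(67)
  sim <- simulate_irr_cohort(6000, table3_multipliers("ED"),
                             dispersion = 1, seed = 67)
  f <- fit_nb_regression(sim, "count", covariates = NULL)
  same <- pairwise_segment_test(f, "END_OF_LIFE", "END_OF_LIFE")
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  all_pairs <- pairwise_segment_tests(f)
  expect_equal(nrow(all_pairs), 15)
  expect_true(all(all_pairs$df == 1))
  joint <- pairwise_segment_tests(f, method = "joint")
  expect_true(all(joint$df[joint$seg_a != "MOSTLY_HEALTHY" &
                             joint$seg_b != "MOSTLY_HEALTHY"] == 2))

  # under equal true rates the contrast test rejects at ~alpha
  set.seed(68)
  rej <- mean(replicate(200, {
    s <- simulate_irr_cohort(1200, dispersion = 0.5,
                             seed = sample.int(1e6, 1))
    fit <- fit_nb_regression(s, "count", covariates = NULL)
    pairwise_segment_test(fit, "SERIOUS_ACUTE", "STABLE_CHRONIC")$p_value < 0.05
  }))
  expect_gte(rej, 0.02)
  expect_lte(rej, 0.10)
})
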