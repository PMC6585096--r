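#' Per-patient follow-up encounter counts
#'
#' Counts each patient's encounters of each kind inside the closed follow-up
#' window (default 2013-01-01 to 2015-12-31). Patients with no encounters in
#' the window get explicit zero counts — most patients have zero utilization,
#' which is why the count models downstream are negative binomial.
#'
#' @param encounters encounter tibble.
#' @param patient_ids character vector (or patient tibble) defining the count
#'   universe; patients absent from `encounters` get zeros.
#' @param window closed Date interval, default the follow-up window.
#' @return Tibble `patient_id`, `ED`, `SOC`, `INPATIENT`.
#' @export
aggregate_counts <- function(encounters, patient_ids,
                             window = c(study_dates()$entry,
                                        study_dates()$study_end)) {
  if (is.data.frame(patient_ids)) patient_ids <- patient_ids$patient_id
  window <- as.Date(window)
  base <- tibble(patient_id = patient_ids)
  wide <- encounters |>
    filter(.data$date >= window[1], .data$date <= window[2]) |>
    count(.data$patient_id, .data$kind) |>
    tidyr::pivot_wider(names_from = "kind", values_from = "n",
                       values_fill = 0L)
  for (k in setdiff(encounter_kinds(), names(wide))) wide[[k]] <- 0L
  base |>
    left_join(wide, by = "patient_id") |>
    mutate(across(dplyr::all_of(encounter_kinds()),
                  ~ ifelse(is.na(.x), 0L, as.integer(.x))))
}

#' Segment-level utilization summary
#'
#' Builds the per-segment and overall utilization table: for each outcome
#' (ED, SOC, INPATIENT) the total encounter count, total patient-days of
#' follow-up (the sum of survival times), the rate per 1000 patient-days,
#' the per-patient mean and SD, and the percentage of patients with any use.
#' Segment totals and patient-days are conserved: they sum exactly to the
#' `All` row.
#'
#' @param counts tibble from [aggregate_counts()].
#' @param survival tibble from [survival_records()].
#' @param segments tibble (`patient_id`, `segment`).
#' @return Tibble keyed by `outcome` and `segment` (including an `"All"`
#'   level) with `n_patients`, `total_count`, `patient_days`,
#'   `rate_per_1000_days`, `mean`, `sd`, `pct_any`.
#' @export
summarize_utilization <- function(counts, survival, segments) {
  joined <- counts |>
    left_join(select(survival, "patient_id", "time_days"), by = "patient_id") |>
    left_join(segments, by = "patient_id")
  if (anyNA(joined$time_days)) data_error("patient missing a survival record")
  if (anyNA(joined$segment)) data_error("patient missing a segment label")
  long <- joined |>
    tidyr::pivot_longer(dplyr::all_of(encounter_kinds()),
                        names_to = "outcome", values_to = "count")
  one_level <- function(d, label) {
    d |>
      group_by(.data$outcome) |>
      summarise(n_patients = dplyr::n(),
                total_count = sum(.data$count),
                patient_days = sum(.data$time_days),
                mean = mean(.data$count),
                sd = sd(.data$count),
                pct_any = pct(sum(.data$count >= 1), dplyr::n()),
                .groups = "drop") |>
      mutate(segment = label, .before = 1)
  }
  per_seg <- long |>
    split(long$segment) |>
    purrr::imap(~ one_level(.x, .y)) |>
    bind_rows()
  all_row <- one_level(long, "All")
  out <- bind_rows(per_seg, all_row) |>
    mutate(rate_per_1000_days = rate_per_1000(.data$total_count,
                                              .data$patient_days),
           segment = factor(.data$segment, levels = c(segment_levels(), "All"))) |>
    select("outcome", "segment", "n_patients", "total_count", "patient_days",
           "rate_per_1000_days", "mean", "sd", "pct_any") |>
    arrange(.data$outcome, .data$segment)
  out
}

#' Bivariate segment comparisons
#'
#' Compares a baseline variable across segments: Pearson chi-square for a
#' categorical variable (on the segment-by-level contingency table) and
#' one-way ANOVA for a continuous variable, mirroring the standard bivariate
#' screen before the adjusted count models.
#'
#' @param data tibble with a `segment` column and the variable.
#' @param var name of the variable column (string).
#' @return One-row tibble `variable`, `method`, `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' d <- tibble::tibble(segment = rep(c("A", "B"), each = 30),
#'                     x = c(rnorm(30), rnorm(30, 1)))
#' bivariate_test(d, "x")
bivariate_test <- function(data, var) {
  g <- factor(data$segment)
  if (nlevels(droplevels(g)) < 2) config_error("need at least 2 segments")
  x <- data[[var]]
  if (is.numeric(x)) {
    fit <- aov(x ~ g)
    s <- summary(fit)[[1]]
    tibble(variable = var, method = "anova",
           statistic = s[["F value"]][1],
           df = s[["Df"]][1], p_value = s[["Pr(>F)"]][1])
  } else {
    tab <- table(droplevels(g), factor(x))
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (ncol(tab) < 2 || any(expected == 0)) {
      abort("degenerate contingency table: expected cell count of 0",
            class = "popseg_error_degenerate")
    }
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    tibble(variable = var, method = "chi-square",
           statistic = unname(ct$statistic),
           df = unname(ct$parameter), p_value = ct$p.value)
  }
}

#' Negative binomial utilization regression
#'
#' Fits the adjusted count model for one outcome: an NB2 regression (variance
#' mu + alpha * mu^2) with log link, segment indicators with Mostly Healthy
#' as the reference level, optional covariates, and the log of each patient's
#' survival time as an exposure offset (so coefficients are log rate ratios).
#' Exposure is floored at one day before the log so that patients who die on
#' the entry date stay in the model.
#'
#' By default the dispersion alpha is estimated jointly with the coefficients
#' by maximum likelihood ([MASS::glm.nb()]). Supplying `dispersion` fixes
#' alpha instead; `dispersion = 0` fits the Poisson limit.
#'
#' @param data tibble with columns `segment`, the outcome count, the exposure
#'   days, and any covariates.
#' @param outcome name of the count column (string).
#' @param covariates character vector of adjustment columns (default age,
#'   gender, ethnicity; add past-utilization columns when available).
#' @param exposure name of the exposure-days column.
#' @param dispersion `NULL` (estimate alpha by ML) or a fixed alpha `>= 0`.
#' @return Object of class `popseg_nb` with elements `coefficients` (tidy
#'   table), `irr` (per-segment IRRs with Wald 95% CIs and p-values),
#'   `dispersion_alpha`, `converged`, `loglik`, `outcome`, and the underlying
#'   `fit`. [tidy()] returns the coefficient table, [glance()] the fit
#'   summary.
#' @export
#' @examples
#' sim <- simulate_irr_cohort(
#'   1200, setNames(c(1, 2, 1, 1, 1, 1), segment_levels()), seed = 2)
#' fit <- fit_nb_regression(sim, "count", covariates = NULL)
#' tidy(fit)
fit_nb_regression <- function(data, outcome,
                              covariates = c("age", "gender", "ethnicity"),
                              exposure = "exposure_days",
                              dispersion = NULL) {
  need <- c("segment", outcome, exposure, covariates)
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    abort(paste0("missing model column(s): ", paste(miss, collapse = ", ")),
          class = "popseg_error_model")
  }
  if (any(data[[exposure]] <= 0 & data[[outcome]] > 0)) {
    abort("positive count with nonpositive exposure", class = "popseg_error_model")
  }
  md <- data
  present <- segment_levels()[segment_levels() %in% unique(as.character(md$segment))]
  if (!"MOSTLY_HEALTHY" %in% present) {
    abort("reference segment MOSTLY_HEALTHY absent from the data",
          class = "popseg_error_model")
  }
  md$.segment <- stats::relevel(factor(as.character(md$segment),
                                       levels = present),
                                ref = "MOSTLY_HEALTHY")
  md$.off <- log(pmax(md[[exposure]], 1))
  seg_term <- if (length(present) >= 2) ".segment" else NULL
  rhs <- paste(c(seg_term, covariates, "1"), collapse = " + ")
  fml <- as.formula(paste0("`", outcome, "` ~ ", rhs, " + offset(.off)"))

  if (is.null(dispersion)) {
    fit <- suppressWarnings(MASS::glm.nb(fml, data = md))
    alpha <- 1 / fit$theta
    # convergence reports the IRLS fit; a dispersion estimate pinned at the
    # Poisson boundary (huge theta) is recorded but is not a failure
    converged <- isTRUE(fit$converged)
  } else if (dispersion == 0) {
    fit <- stats::glm(fml, data = md, family = stats::poisson())
    alpha <- 0
    converged <- isTRUE(fit$converged)
  } else {
    fit <- stats::glm(fml, data = md,
                      family = MASS::negative.binomial(theta = 1 / dispersion))
    alpha <- dispersion
    converged <- isTRUE(fit$converged)
  }
  cf <- coef(fit)
  if (anyNA(cf)) {
    abort("rank-deficient design: some coefficients are not estimable",
          class = "popseg_error_model")
  }
  se <- sqrt(diag(vcov(fit)))
  coefs <- tibble(term = names(cf), estimate = unname(cf),
                  std_error = unname(se[names(cf)]),
                  statistic = unname(cf / se[names(cf)]),
                  p_value = 2 * pnorm(-abs(unname(cf / se[names(cf)]))))

  seg_terms <- paste0(".segment", setdiff(levels(md$.segment), "MOSTLY_HEALTHY"))
  z <- qnorm(0.975)
  irr <- coefs |>
    filter(.data$term %in% seg_terms) |>
    mutate(segment = sub("^\\.segment", "", .data$term),
           irr = exp(.data$estimate),
           ci_low = exp(.data$estimate - z * .data$std_error),
           ci_high = exp(.data$estimate + z * .data$std_error)) |>
    select("segment", "irr", "ci_low", "ci_high", "p_value")
  irr <- bind_rows(
    tibble(segment = "MOSTLY_HEALTHY", irr = 1,
           ci_low = NA_real_, ci_high = NA_real_, p_value = NA_real_),
    irr) |>
    mutate(segment = as_segment(.data$segment)) |>
    arrange(.data$segment)

  structure(
    list(coefficients = coefs, irr = irr, dispersion_alpha = alpha,
         converged = converged, loglik = as.numeric(logLik(fit)),
         outcome = outcome, fit = fit),
    class = "popseg_nb")
}

#' @export
print.popseg_nb <- function(x, ...) {
  cat("<popseg_nb> outcome:", x$outcome,
      " alpha:", format(x$dispersion_alpha, digits = 4),
      " converged:", x$converged, "\n")
  print(x$irr)
  invisible(x)
}

#' @method tidy popseg_nb
#' @export
tidy.popseg_nb <- function(x, ...) x$coefficients

#' @method glance popseg_nb
#' @export
glance.popseg_nb <- function(x, ...) {
  tibble(outcome = x$outcome, dispersion_alpha = x$dispersion_alpha,
         loglik = x$loglik, converged = x$converged,
         nobs = stats::nobs(x$fit))
}

nb_segment_term <- function(fit, segment) {
  if (segment == "MOSTLY_HEALTHY") return(NA_character_)
  paste0(".segment", segment)
}

#' Pairwise segment comparison within a fitted count model
#'
#' Wald chi-square test that two segments share the same rate, based on the
#' fitted coefficient vector and covariance matrix. Two constructions are
#' available: `"contrast"` (1 df) tests equality of the two segment
#' coefficients; `"joint"` (2 df) tests that both coefficients are
#' simultaneously zero, i.e. that both segments equal the reference rate.
#' When one of the pair is the reference segment both reduce to a 1-df test
#' of the other coefficient.
#'
#' @param fit a `popseg_nb`.
#' @param seg_a,seg_b segment codes.
#' @param method `"contrast"` (default) or `"joint"`.
#' @return One-row tibble `seg_a`, `seg_b`, `statistic`, `df`, `p_value`.
#' @export
pairwise_segment_test <- function(fit, seg_a, seg_b,
                                  method = c("contrast", "joint")) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "popseg_nb"))
  seg_a <- as.character(seg_a); seg_b <- as.character(seg_b)
  if (identical(seg_a, seg_b)) {
    return(tibble(seg_a = seg_a, seg_b = seg_b, statistic = 0,
                  df = 1L, p_value = 1))
  }
  cf <- coef(fit$fit); V <- vcov(fit$fit)
  ta <- nb_segment_term(fit, seg_a); tb <- nb_segment_term(fit, seg_b)
  present <- stats::na.omit(c(ta, tb))
  if (!all(present %in% names(cf))) {
    abort("segment not present in the fitted model", class = "popseg_error_model")
  }
  if (method == "joint" && !is.na(ta) && !is.na(tb)) {
    b <- cf[c(ta, tb)]
    Vs <- V[c(ta, tb), c(ta, tb)]
    stat <- as.numeric(t(b) %*% solve(Vs) %*% b)
    df <- 2L
  } else {
    # contrast beta_a - beta_b (reference coefficient is 0 with no variance)
    ca <- if (is.na(ta)) 0 else cf[[ta]]
    cb <- if (is.na(tb)) 0 else cf[[tb]]
    va <- if (is.na(ta)) 0 else V[ta, ta]
    vb <- if (is.na(tb)) 0 else V[tb, tb]
    cab <- if (is.na(ta) || is.na(tb)) 0 else V[ta, tb]
    stat <- (ca - cb)^2 / (va + vb - 2 * cab)
    df <- 1L
  }
  tibble(seg_a = seg_a, seg_b = seg_b, statistic = stat, df = df,
         p_value = pchisq(stat, df, lower.tail = FALSE))
}

#' All 15 pairwise segment tests
#'
#' @param fit a `popseg_nb` fitted on all six segments.
#' @param method see [pairwise_segment_test()].
#' @param bonferroni multiply p-values by the number of pairs (off by
#'   default; raw p-values are the reporting convention here).
#' @return Tibble with one row per unordered segment pair.
#' @export
pairwise_segment_tests <- function(fit, method = c("contrast", "joint"),
                                   bonferroni = FALSE) {
  method <- match.arg(method)
  segs <- as.character(fit$irr$segment)
  pairs <- utils::combn(segs, 2)
  out <- purrr::map(seq_len(ncol(pairs)), function(i) {
    pairwise_segment_test(fit, pairs[1, i], pairs[2, i], method = method)
  }) |> bind_rows()
  if (bonferroni) {
    out <- out |> mutate(p_value = pmin(.data$p_value * dplyr::n(), 1))
  }
  out
}
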