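#' Presentation formatting helpers
#'
#' Rounding conventions for rendered tables: percentages to 1 decimal place,
#' rates and IRRs to 2, p-values below 0.001 rendered as `"< 0.001"`.
#' Rendering is presentation-only; all analysis objects keep full precision.
#' @param x numeric vector.
#' @param d decimal places.
#' @return Character vector.
#' @export
fmt_num <- function(x, d = 2) formatC(x, format = "f", digits = d, big.mark = ",")

#' @rdname fmt_num
#' @export
fmt_count <- function(x) formatC(x, format = "d", big.mark = ",")

#' @rdname fmt_num
#' @export
fmt_p <- function(x) ifelse(x < 0.001, "< 0.001", formatC(x, format = "f", digits = 3))

age_bands <- function(age) {
  cut(age, breaks = c(21, 31, 41, 51, 61, 71, 81, 91, Inf),
      right = FALSE,
      labels = c("21-30", "31-40", "41-50", "51-60", "61-70", "71-80",
                 "81-90", ">90"))
}

seg_cols <- function() c(as.character(segment_levels()), "All")

#' Baseline demographics and utilization table
#'
#' Renders the baseline-year summary by segment: per-segment n (%), age mean
#' (SD) and ten-year age bands, gender, ethnicity, and baseline ED / SOC /
#' admission use (median (IQR) and % with any), with chi-square / ANOVA
#' p-values comparing segments.
#'
#' @param patients eligible patient tibble.
#' @param segments tibble (`patient_id`, `segment`).
#' @param encounters encounter tibble (baseline window rows are used).
#' @param rules rule set supplying the baseline window.
#' @return Tibble with a `variable` column, one rendered column per segment,
#'   an `All` column and a `p_value` column.
#' @export
build_table1 <- function(patients, segments, encounters,
                         rules = default_rules()) {
  w <- rules$baseline_window
  base_counts <- aggregate_counts(encounters, patients$patient_id, window = w)
  d <- patients |>
    left_join(segments, by = "patient_id") |>
    left_join(base_counts, by = "patient_id")
  if (anyNA(d$segment)) data_error("unsegmented patient in table input")
  n_all <- nrow(d)
  groups <- c(setNames(as.list(segment_levels()), segment_levels()),
              list(All = segment_levels()))

  cell <- function(f) {
    vapply(seg_cols(), function(gc) {
      di <- d |> filter(as.character(.data$segment) %in% groups[[gc]])
      f(di)
    }, character(1))
  }
  pv <- function(var, data = d) {
    if (nlevels(droplevels(factor(data$segment))) < 2) return(NA_real_)
    bivariate_test(data, var)$p_value
  }
  med_iqr <- function(x) {
    q <- quantile(x, c(0.25, 0.5, 0.75), type = 2)
    sprintf("%d (%d-%d)", as.integer(q[2]), as.integer(q[1]), as.integer(q[3]))
  }
  rows <- list()
  rows[["Total (%)"]] <- list(
    cells = cell(function(di) sprintf("%s (%s%%)", fmt_count(nrow(di)),
                                      fmt_num(pct(nrow(di), n_all), 1))),
    p = NA_real_)
  d$.band <- as.character(age_bands(d$age_2012))
  rows[["Age mean (SD)"]] <- list(
    cells = cell(function(di) sprintf("%s (%s)", fmt_num(mean(di$age_2012), 1),
                                      fmt_num(sd(di$age_2012), 1))),
    p = pv("age_2012"))
  for (b in levels(age_bands(21))) {
    rows[[paste0("Age ", b, " (%)")]] <- list(
      cells = cell(function(di) sprintf("%s (%s%%)",
                                        fmt_count(sum(di$.band == b)),
                                        fmt_num(pct(sum(di$.band == b),
                                                    max(nrow(di), 1)), 1))),
      p = if (b == levels(age_bands(21))[1]) pv(".band") else NA_real_)
  }
  rows[["Male (%)"]] <- list(
    cells = cell(function(di) sprintf("%s (%s%%)",
                                      fmt_count(sum(di$gender == "male")),
                                      fmt_num(pct(sum(di$gender == "male"),
                                                  max(nrow(di), 1)), 1))),
    p = pv("gender"))
  for (e in c("Chinese", "Malay", "Indian", "Others")) {
    rows[[paste0(e, " (%)")]] <- list(
      cells = cell(function(di) sprintf("%s (%s%%)",
                                        fmt_count(sum(di$ethnicity == e)),
                                        fmt_num(pct(sum(di$ethnicity == e),
                                                    max(nrow(di), 1)), 1))),
      p = if (e == "Chinese") pv("ethnicity") else NA_real_)
  }
  for (k in encounter_kinds()) {
    lab <- c(ED = "ED visits", SOC = "SOC visits",
             INPATIENT = "Hospital admissions")[[k]]
    rows[[paste0(lab, " 2012 median (IQR)")]] <- list(
      cells = cell(function(di) med_iqr(di[[k]])), p = pv(k))
    d$.any <- factor(d[[k]] >= 1, levels = c(FALSE, TRUE))
    rows[[paste0(lab, " 2012 any (%)")]] <- list(
      cells = cell(function(di) sprintf("%s (%s%%)",
                                        fmt_count(sum(di[[k]] >= 1)),
                                        fmt_num(pct(sum(di[[k]] >= 1),
                                                    max(nrow(di), 1)), 1))),
      p = pv(".any"))
  }
  tb <- purrr::imap(rows, function(r, nm) {
    as_tibble(c(list(variable = nm), setNames(as.list(r$cells), seg_cols()),
                list(p_value = if (is.na(r$p)) "" else fmt_p(r$p))))
  }) |> bind_rows()
  tb
}

#' Utilization summary table
#'
#' Renders the follow-up utilization summary (one block per outcome: grand
#' total, rate per 1000 patient-days to 2 decimals, mean (SD), % with any
#' use) plus the total patient-days row, with segments as columns.
#'
#' @param summary output of [summarize_utilization()].
#' @return Rendered tibble with a `row` column and one column per segment
#'   plus `All`.
#' @export
build_table2 <- function(summary) {
  get_cell <- function(outc, seg, f) {
    r <- summary |> filter(.data$outcome == outc,
                           as.character(.data$segment) == seg)
    if (nrow(r) == 0) "0" else f(r)
  }
  cols <- seg_cols()
  row_for <- function(label, outc, f) {
    as_tibble(c(list(row = label),
                setNames(lapply(cols, function(s) get_cell(outc, s, f)), cols)))
  }
  days_row <- row_for("Total no. of patient days", "ED",
                      function(r) fmt_count(r$patient_days))
  blocks <- purrr::map(encounter_kinds(), function(k) {
    lab <- c(ED = "ED visits", SOC = "SOC visits",
             INPATIENT = "Hospital admissions")[[k]]
    bind_rows(
      row_for(paste0(lab, ": grand total"), k,
              function(r) fmt_count(r$total_count)),
      row_for(paste0(lab, ": no. per 1000 patient days"), k,
              function(r) fmt_num(r$rate_per_1000_days, 2)),
      row_for(paste0(lab, ": mean (SD)"), k,
              function(r) sprintf("%s (%s)", fmt_num(r$mean, 2),
                                  fmt_num(r$sd, 2))),
      row_for(paste0(lab, ": any use (%)"), k,
              function(r) fmt_num(r$pct_any, 1))
    )
  })
  bind_rows(days_row, blocks)
}

#' Incidence-rate-ratio table
#'
#' Renders the adjusted negative binomial results, one block per outcome:
#' IRR to 2 decimals with 95% CI and p-value, reference segment rendered as
#' `"Reference"`.
#'
#' @param fits named list of `popseg_nb` fits, one per outcome.
#' @return Rendered tibble `outcome`, `segment`, `irr`, `ci95`, `p_value`.
#' @export
build_table3 <- function(fits) {
  if (!all(encounter_kinds() %in% names(fits))) {
    abort("fits must be named list covering ED, SOC and INPATIENT",
          class = "popseg_error_structure")
  }
  purrr::map(encounter_kinds(), function(k) {
    f <- fits[[k]]
    f$irr |>
      mutate(outcome = k,
             segment = as.character(.data$segment),
             irr_chr = ifelse(as.character(.data$segment) == "MOSTLY_HEALTHY",
                              "Reference", fmt_num(.data$irr, 2)),
             ci95 = ifelse(as.character(.data$segment) == "MOSTLY_HEALTHY", "",
                           sprintf("(%s, %s)", fmt_num(.data$ci_low, 2),
                                   fmt_num(.data$ci_high, 2))),
             p_chr = ifelse(as.character(.data$segment) == "MOSTLY_HEALTHY",
                            "", fmt_p(.data$p_value))) |>
      select("outcome", "segment", irr = "irr_chr", "ci95", p_value = "p_chr")
  }) |> bind_rows()
}
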