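test_that("eligibility keeps adults with baseline-year utilization only", {
  enc2012 <- tibble::tibble(patient_id = c("a", "b"),
                            date = as.Date("2012-05-01"), kind = "SOC")
  enc2013 <- tibble::tibble(patient_id = "c",
                            date = as.Date("2013-05-01"), kind = "ED")
  pats <- tibble::tibble(
    patient_id = c("a", "b", "c"),
    age_2012 = c(20L, 21L, 50L),
    gender = "female", ethnicity = "Chinese",
    death_date = as.Date(NA), chronic_conditions = "",
    serious_acute = FALSE, end_of_life_condition = FALSE)
  enc <- dplyr::bind_rows(enc2012, enc2013)
  kept <- filter_eligible(pats, enc)
  expect_identical(kept$patient_id, "b")

  # brute-force oracle over the encounter table
  w <- default_rules()$baseline_window
  oracle <- pats$patient_id[pats$age_2012 >= 21 & vapply(
    pats$patient_id,
    function(id) any(enc$patient_id == id & enc$date >= w[1] & enc$date <= w[2]),
    logical(1))]
  expect_identical(kept$patient_id, unname(oracle))

  pats$age_2012[1] <- NA
  expect_error(filter_eligible(pats, enc), class = "popseg_error_data")
})

test_that("admission counting respects type filter and window boundaries", {
  w <- as.Date(c("2012-01-01", "2012-12-31"))
  mk <- function(dates, kinds) {
    tibble::tibble(patient_id = "x", date = as.Date(dates), kind = kinds)
  }
  expect_equal(count_admissions_in_window(
    mk(rep("2012-03-01", 3), rep("INPATIENT", 3)), w), 3)
  expect_equal(count_admissions_in_window(
    mk(rep("2012-03-01", 7), c(rep("INPATIENT", 2), rep("ED", 5))), w), 2)
  expect_equal(count_admissions_in_window(
    mk(c("2011-12-31", "2012-01-01", "2012-06-15", "2012-12-31"),
       rep("INPATIENT", 4)), w), 3)
  expect_equal(count_admissions_in_window(mk(character(), character()), w), 0)
})

test_that("single patients classify per the default predicates and precedence", {
  arch <- archetype_cohort()
  for (id in arch$patients$patient_id) {
    got <- classify_patient(arch$patients[arch$patients$patient_id == id, ],
                            arch$encounters[arch$encounters$patient_id == id, ])
    expect_identical(as.character(got), unname(arch$truth[id]), label = id)
  }
  # end-of-life flag dominates even with 4 admissions
  eol <- arch$patients[arch$patients$patient_id == "eol", ]
  enc <- tibble::tibble(patient_id = "eol",
                        date = as.Date("2012-03-01") + 1:4 * 10,
                        kind = "INPATIENT")
  expect_identical(as.character(classify_patient(eol, enc)), "END_OF_LIFE")
})

test_that("frequent-admission threshold is sharp at 3 admissions", {
  arch <- archetype_cohort()
  ccnf <- arch$patients[arch$patients$patient_id == "ccnf", ]
  adm <- function(k) tibble::tibble(
    patient_id = "ccnf", date = as.Date("2012-02-01") + seq_len(k) * 7,
    kind = "INPATIENT")
  expect_identical(as.character(classify_patient(ccnf, adm(2))),
                   "COMPLEX_CHRONIC_NO_FREQ")
  expect_identical(as.character(classify_patient(ccnf, adm(3))),
                   "COMPLEX_CHRONIC_FREQ")
  # monotonicity: extra admissions never demote a frequent admitter
  for (k in 4:8) {
    expect_identical(as.character(classify_patient(ccnf, adm(k))),
                     "COMPLEX_CHRONIC_FREQ")
  }
})

test_that("segmentation is a partition of any generated cohort", {
  co <- generate_cohort(cohort_config(2000, seed = 31))
  seg <- segment_cohort(co$patients, co$encounters)
  expect_equal(nrow(seg), nrow(co$patients))
  expect_false(anyNA(seg$segment))
  expect_equal(sum(table(seg$segment)), nrow(co$patients))
  expect_identical(sort(seg$patient_id), sort(co$patients$patient_id))
})

test_that("single-predicate patients are precedence-invariant", {
  arch <- archetype_cohort()
  # strip the end-of-life archetype's chronic condition so that mh, sa, sc
  # and eol each satisfy exactly one non-catch-all predicate; random
  # precedence orders (catch-all kept last) must not change their labels
  arch$patients$chronic_conditions[arch$patients$patient_id == "eol"] <- ""
  single <- c("mh", "sa", "sc", "eol")
  set.seed(41)
  for (i in 1:20) {
    ord <- sample(setdiff(segment_levels(), "MOSTLY_HEALTHY"))
    rules <- default_rules(precedence = c(ord, "MOSTLY_HEALTHY"))
    seg <- segment_cohort(arch$patients, arch$encounters, rules)
    got <- setNames(as.character(seg$segment), seg$patient_id)
    expect_identical(got[single], arch$truth[single])
  }
})

test_that("mis-specified rules and duplicate ids are rejected", {
  expect_error(default_rules(precedence = c("MOSTLY_HEALTHY", "END_OF_LIFE",
                                            "COMPLEX_CHRONIC_FREQ",
                                            "COMPLEX_CHRONIC_NO_FREQ",
                                            "SERIOUS_ACUTE", "STABLE_CHRONIC")),
               regexp = "catch-all", class = "popseg_error_config")
  expect_error(default_rules(frequent_admission_threshold = 0),
               class = "popseg_error_config")
  arch <- archetype_cohort()
  dup <- dplyr::bind_rows(arch$patients, arch$patients[1, ])
  expect_error(segment_cohort(dup, arch$encounters),
               class = "popseg_error_data")
})

test_that("rules YAML round-trips", {
  rules <- default_rules(frequent_admission_threshold = 4)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_rules(rules, path)
  back <- read_rules(path)
  expect_equal(back$frequent_admission_threshold, 4L)
  expect_equal(back$precedence, rules$precedence)
  expect_equal(back$baseline_window, rules$baseline_window)
})
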