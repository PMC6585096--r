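---
title: "Methods: six-segment population segmentation and its longitudinal evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: six-segment population segmentation and its longitudinal evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popseg)
```

`popseg` packages three things: a rule engine that assigns adult patients
to one of six expert-defined population segments from baseline-year EHR
data; the longitudinal evaluation pipeline (three-year utilization and
mortality by segment); and a calibrated synthetic cohort generator that
makes the whole pipeline exercisable, testable and reproducible without
access to patient-level data. This vignette records the model choices,
their assumptions and their defaults.

## The segmentation rule engine

Eligibility: adults (age ≥ 21 in the baseline year, 2012) with at least
one encounter of any type dated in the baseline year. Both criteria are
applied by `filter_eligible()`; patients with encounters only outside the
baseline year are excluded.

Each eligible patient is labelled with the **first** segment in a
precedence list whose predicate holds:

| precedence | segment | default predicate |
|---|---|---|
| 1 | End of Life | end-of-life condition flag set |
| 2 | Complex Chronic, Frequent Admissions | ≥ 2 recognized chronic categories **and** ≥ 3 baseline inpatient admissions |
| 3 | Complex Chronic, no Frequent Admissions | ≥ 2 recognized chronic categories, < 3 admissions |
| 4 | Serious Acute | serious-acute condition flag set |
| 5 | Stable Chronic | ≥ 1 recognized chronic category |
| 6 | Mostly Healthy | always true (catch-all, must be last) |

Design choices behind this table, all configurable via `default_rules()`:

* **Precedence.** The framework requires the six segments to be
  non-overlapping but does not dictate a tie-break for patients satisfying
  several predicates. We order severity-descending (End of Life dominates
  everything; complex chronic dominates serious acute and stable chronic),
  which matches the framework's intent of assigning each patient to their
  most care-intensive stratum. Any permutation keeping the catch-all last
  is accepted; a property test verifies that patients satisfying exactly
  one predicate are invariant to reordering.
* **Frequent admissions.** The threshold is 3+ inpatient admissions in the
  past 12 months, the published proxy for high-cost users. The lookback is
  implemented as the 2012 *calendar year* (the baseline encounter year),
  not a rolling 365-day window per encounter, matching the baseline-year
  framing of the evaluation; both the window and the threshold are
  configurable. ED and SOC encounters never count toward it.
* **Stable vs Complex Chronic.** The public description of the framework
  does not state whether the distinction rests on condition counts or on
  disease-control status. We use a count-based default — one recognized
  chronic category is Stable, two or more is Complex — as an explicit,
  documented assumption (`complex_min_chronic_count`), not established
  fact.
* **Clinical content.** The detailed clinical definitions of the
  serious-acute and end-of-life categories and the chronic-disease list
  are not published in full; they are represented as boolean flags and a
  configurable chronic-category vocabulary.
  `default_chronic_vocabulary()` ships eight common chronic categories
  (diabetes, hypertension, hyperlipidemia, ischemic heart disease, stroke,
  COPD/asthma, CKD, heart failure) for simulation; real deployments map
  their own coding systems into the vocabulary.

The engine is total: `segment_cohort()` always returns exactly one label
per patient (the catch-all guarantees it), and the partition property —
segment sizes summing to the cohort size, sharpness of the admission
threshold, monotonicity in added admissions — is enforced by tests.

## Survival construction, Kaplan–Meier and log-rank

Follow-up runs from a fixed entry date (2013-01-01) to the administrative
study end (2015-12-31), i.e. `as.integer(study_end - entry)` = 1094 days.
`survival_records()` encodes the rules:

* death on or before the study end → `time = death − entry` days (whole
  calendar days), `event = 1`;
* otherwise → `time = 1094`, `event = 0`. Deaths *after* the study end
  are censored at 1094, because follow-up simply does not observe them.
* Deaths recorded on the entry date itself get time 0 with an event and
  are retained; the count models floor their exposure to one day so the
  log offset stays finite.
* Patients who die before entry never enter follow-up; the cohort
  constructor drops them and reports the count (the single-patient
  primitive treats this as an error instead).

Kaplan–Meier estimation and the K-group log-rank test are delegated to
the `survival` package (`survfit`, `survdiff`) behind `km_estimate()` /
`log_rank_test()`; the test suite cross-checks both against independent
brute-force risk-set computations, and verifies the no-censoring limit
(KM = empirical survival), order/duplication invariance, convergence to a
closed-form exponential, and the type-I error of the log-rank test over
1000 null replicates. p-values are kept at machine precision throughout;
the "< 0.001" convention is applied only when rendering tables.

## The utilization models

Follow-up counts (ED, SOC, admissions in 2013–2015) are summarised per
segment as totals, rates per 1000 patient-days (total count × 1000 /
summed survival days), means/SDs and the share with any use. Most
patients have zero utilization, so the adjusted model for each outcome is
an NB2 negative binomial regression (variance μ + αμ², log link) with:

* segment indicators, reference Mostly Healthy — exp(β) is the IRR;
* covariates: age (continuous years by default; banding is available in
  the table builders), gender, ethnicity;
* **past utilization**: the published model adjusts for "past hospital
  utilization" without saying whether that is one covariate or several;
  we enter all three baseline-2012 counts (ED, SOC, admissions) together
  as the conservative reading, configurable through the `covariates`
  argument;
* offset `log(pmax(exposure_days, 1))`, the survival time, converting
  modelled counts to rates;
* dispersion α estimated by maximum likelihood (`MASS::glm.nb`), or fixed
  by the caller (`dispersion = 0` gives the Poisson limit — the test
  suite checks coefficient agreement to 1e-6 there). The convergence flag
  reports the IRLS fit; a dispersion estimate pinned at the Poisson
  boundary on equidispersed data is not treated as failure.

Pairwise segment comparisons: the published analysis mentions a
"two-degree-freedom chi-square test between each pair of segments", which
is internally ambiguous — an equality contrast between two coefficients
has 1 df. `pairwise_segment_test()` therefore implements both: the
default `"contrast"` method (1 df, Wald test of β_A = β_B using the full
covariance) and a `"joint"` method (2 df, β_A = β_B = 0). Neither is
asserted to be the published construction. All 15 pairs are reported with
raw p-values; a Bonferroni toggle exists but is off by default, matching
the published reporting.

## The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes,
with defaults calibrated to the published evaluation cohort
(`reference_*()` functions):

* **Mixture**: segment assignment is multinomial with shares
  58.8 / 24.5 / 5.3 / 10.7 / 0.5 / 0.2 %.
* **Demographics**: per-segment normal ages (published means/SDs)
  truncated to [21, 100] and rounded; Bernoulli gender and categorical
  ethnicity with the published per-segment fractions (renormalised to sum
  to one).
* **Baseline 2012 encounters** are generated to *satisfy*, not merely
  correlate with, the segment definitions: a frequent-admitter draws
  3 + Poisson extra admissions, every other patient's admissions are
  capped at 2; chronic-condition counts are forced to the defining ranges
  (0 / exactly 1 / ≥ 2); the serious-acute and end-of-life flags are set
  iff the segment requires them; and every patient receives at least one
  baseline encounter so the whole cohort is eligible. This makes the
  generator→classifier round trip exact (100 % label agreement at any
  seed), which is the module's testability anchor. Baseline ED/SOC means
  are package defaults chosen to be consistent with the published
  baseline medians and any-use percentages.
* **Mortality**: death times are piecewise exponential with knots at the
  follow-up year boundaries (days 365/730/1094) and hazards solved from
  the configured yearly survival, the simplest model reproducing the
  published yearly survival exactly. Yearly survival is published exactly
  only for End of Life (74.6/64.6/58.2 %) and Complex Chronic with
  Frequent Admissions (81.7/71.0/62.6 %); the other four segments are
  published only as bounds (> 95 %, > 93 %, > 90 % at years 1–3), so the
  defaults use representative values inside those bounds (e.g. Mostly
  Healthy 99.5/99.1/98.7 %).
* **Follow-up utilization**: per outcome, counts are NB2 with mean =
  (segment rate per patient-day) × (realized survived days), thinning the
  process by mortality so no encounter postdates death; encounter dates
  are uniform over the survived window. Default rates are the published
  per-1000-patient-day rates divided by 1000. Default dispersion is α = 3
  for each outcome, matched to the order of magnitude implied by the
  published means and SDs. Outcomes are generated independently given
  segment: within-patient correlation across ED/SOC/admissions is not
  published, so none is imposed — a documented simplification.
* **Seeding**: one master integer seed; every generation stage (and every
  fixed-length sub-draw within a stage) has its own deterministic
  sub-stream, with draws in patient order, so the same seed yields
  byte-identical output files and enlarging the cohort never perturbs
  earlier patients' records.

What passing tests on synthetic cohorts show — and what they do not: they
demonstrate that the pipeline's estimators recover the quantities the
generator encodes (rates, rate ratios, survival) at the configured
magnitudes, and that the rule engine and bookkeeping are exact. They do
not validate the framework on real EHR data: the generator has no coded
diagnosis streams, no comorbidity correlation beyond segment membership,
no seasonality, and its covariates are conditionally independent given
segment, so adjusted IRRs estimated on a default synthetic cohort need
not (and generally will not) equal the published adjusted IRRs, which
reflect real-world confounding.

## The calibrated recovery simulations

The acceptance computations ask a sharper question: *given* a cohort
whose true rate multipliers equal the published IRR columns, does the NB
machinery recover them? `simulate_irr_cohort()` draws a balanced design —
n/6 patients per segment, demographic covariates independent of segment
(hence with zero true effect), full 1094-day exposure, NB2 counts with a
baseline expectation of 1 event per exposure window and α = 1 — so the
estimable truth is exactly the supplied multiplier vector, and the
published values (ED 14.52 and admissions 22.66 for Complex Chronic with
Frequent Admissions, SOC 11.50 for End of Life) are recovered within ±5 %
at n = 60,000. The balanced design carries no baseline-utilization
covariates (they would be degenerate there); the full-cohort pipeline
fits them as described above. The three-year survival check draws 2,000
End-of-Life patients from an exponential law with S(1094) = 0.582
(realised as equal-hazard piecewise segments), censors at day 1094 and
reads the Kaplan–Meier estimate at day 1094 (tolerance ±2 points,
comfortably above the binomial SE of ~1.1 points at that n).

## Numerical conventions and test scales

* Rates are per 1000 patient-days; percentages to 1 decimal, rates and
  IRRs to 2 in rendered tables; p-values below 0.001 render as
  "< 0.001".
* Age bands 21–30, …, 81–90, > 90, closed on the left.
* Wald 95 % CIs: exp(β ± 1.96 SE).
* Exposure floor: one day, applied only inside the count models.
* Test problem sizes are chosen so each check has clear resolving power
  at small cost: mixture shares and rate calibration at n = 100,000
  (where the 5 % calibration band spans ≥ 3 sampling SEs for all but the
  two rarest segments, whose bands are noise-scaled instead), IRR
  recovery at n = 60,000, bias/coverage over 100 cohorts of n = 20,000,
  type-I error studies at 1000 replicates.

## Known limitations

* The chronic-condition vocabulary is a stand-in; no ICD mapping ships.
* Stable-vs-Complex by condition count is an assumption (see above).
* The generator's low-mortality segment survival and baseline encounter
  means are representative defaults, not published values.
* No Cox models, competing risks, confidence bands, zero-inflated or
  hurdle count models, or cost outcomes — all outside the evaluated
  pipeline.
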