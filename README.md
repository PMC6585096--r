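# popseg

Expert-defined population segmentation of EHR cohorts, with longitudinal
evaluation against healthcare utilization and mortality.

Health systems increasingly plan services around *population segments*:
parsimonious, mutually exclusive patient subgroups with similar healthcare
needs. `popseg` implements a six-segment expert-defined framework —
**Mostly Healthy**, **Serious Acute**, **Stable Chronic**, **Complex Chronic
without Frequent Hospital Admissions**, **Complex Chronic with Frequent
Hospital Admissions** (≥ 3 inpatient admissions in the 12-month baseline
window, a proxy for high-cost users), and **End of Life** — as a
precedence-ordered, configurable rule engine applied to baseline-year
patient and encounter tables, together with the full pipeline used to
evaluate whether segment membership predicts three-year utilization and
survival:

* **Survival**: follow-up from entry (2013-01-01) to the study end
  (2015-12-31); a patient who dies on or before the study end contributes
  `death − entry` days with an event, anyone else exactly 1094 censored
  days. Per-segment Kaplan–Meier curves
  S(t) = ∏_{tᵢ ≤ t} (1 − dᵢ/nᵢ) and the K-group log-rank test.
* **Utilization**: per-patient 2013–2015 counts of emergency department
  (ED) attendances, specialist outpatient clinic (SOC) attendances and
  hospital admissions; segment summaries as rates per 1000 patient-days;
  and for each outcome an NB2 negative binomial regression
  (Var = μ + αμ²) with log link, Mostly Healthy as reference, adjustment
  for age, gender, ethnicity and baseline utilization, and log survival
  time as exposure offset, so exp(β_segment) is an incidence rate ratio
  (IRR). All 15 pairwise segment contrasts are Wald chi-square tests.
* **Synthetic cohorts**: a seeded generator whose defaults are calibrated
  to the published evaluation of this framework in a Singapore regional
  health system (819,993 adults): segment mix, demographic marginals,
  per-1000-patient-day follow-up rates, and piecewise-exponential survival
  matching the published yearly survival. Generated baseline records
  *satisfy* the segment definitions by construction, so the classifier
  reproduces the generator's labels exactly (a testable round-trip).

Everything is tidyverse-native: patient and encounter tables in, tibbles
out, `tidy()`/`glance()` on fitted objects, `autoplot()` on curves and
fits.

## Worked example

```r
library(popseg)
library(dplyr)

cfg <- cohort_config(n_patients = 20000, seed = 42)
rep <- run_pipeline(cfg)

count(rep$segments, segment)
#>   segment                     n
#> 1 MOSTLY_HEALTHY          11725
#> 2 SERIOUS_ACUTE            4834
#> 3 STABLE_CHRONIC           1096
#> 4 COMPLEX_CHRONIC_NO_FREQ  2183
#> 5 COMPLEX_CHRONIC_FREQ      119
#> 6 END_OF_LIFE                43
```

The classifier reproduces the configured mixture (58.8 / 24.5 / 5.3 /
10.7 / 0.5 / 0.2 %). The realized per-segment ED rates per 1000
patient-days track the configured calibration closely:

```r
filter(rep$utilization, outcome == "ED") |>
  select(segment, total_count, patient_days, rate_per_1000_days)
#>   segment                 total_count patient_days rate_per_1000_days
#> 1 MOSTLY_HEALTHY                 1605     12730725               0.13
#> 2 SERIOUS_ACUTE                  1479      5230078               0.28
#> 3 STABLE_CHRONIC                  395      1190595               0.33
#> 4 COMPLEX_CHRONIC_NO_FREQ        1870      2295514               0.81
#> 5 COMPLEX_CHRONIC_FREQ            453       104854               4.32
#> 6 END_OF_LIFE                      35        34841               1.00
#> 7 All                            5837     21586607               0.27
```

The log-rank test separates the six survival curves decisively
(chi-square 1346 on 5 df, p < 0.001 at this cohort size), and the rendered
IRR table shows the familiar utilization gradient, e.g. for ED visits:

```r
filter(rep$table3, outcome == "ED")
#>   outcome segment                 irr       ci95             p_value
#> 1 ED      MOSTLY_HEALTHY          Reference ""               ""
#> 2 ED      SERIOUS_ACUTE           2.27      "(2.05, 2.52)"   "< 0.001"
#> 3 ED      STABLE_CHRONIC          2.57      "(2.11, 3.12)"   "< 0.001"
#> 4 ED      COMPLEX_CHRONIC_NO_FREQ 6.47      "(5.45, 7.68)"   "< 0.001"
#> 5 ED      COMPLEX_CHRONIC_FREQ    34.62     "(15.72, 76.26)" "< 0.001"
#> 6 ED      END_OF_LIFE             6.60      "(2.88, 15.12)"  "< 0.001"
```

(IRRs from a synthetic cohort are not expected to match the published
adjusted IRRs numerically — see the methods vignette for what the
generator does and does not emulate.)

A thin command-line wrapper over the same functions lives at
`inst/cli/popseg.R` (`simulate`, `segment`, `run` subcommands).

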