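---
title: "Measuring chronic PPI use and deprescribing on dispensing claims"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring chronic PPI use and deprescribing on dispensing claims}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppicohort)
```

## The problem

Proton pump inhibitors (PPIs) are among the most dispensed drug classes in
primary care, and a large share of long-term use has no maintained
indication. Deprescribing trials need a *control-arm* description of how
chronic use evolves without intervention: how many people are chronically
exposed each year, how many start, and how many stop. Administrative
dispensing claims can answer this, but only after a series of modelling
choices - what counts as "chronic", how refill gaps are handled, how
episodes are delimited - that this package implements as a tested, reusable
pipeline, together with a synthetic claims generator so the entire analysis
runs without access to any confidential claims database.

## The exposure model

Everything rests on one identification rule, applied at **January 1
anchors**:

* Each dispensing of `units` oral doses on day $d$ supplies the closed
  interval $[d,\, d + \mathrm{units} - 1]$ - one unit is one day of
  treatment.
* A patient is a **chronic user** of year $y$ when the trailing quarter
  (October 1 - December 31 of $y-1$, 92 days) contains at least
  $\lceil 0.80 \times 92 \rceil = 74$ dispensed doses, i.e. a *temporal
  coverage* of at least 80%. Coverage is dose-count based
  ($\min(1, \text{doses}/92)$), counted by dispensing date: a box dispensed
  September 30 contributes nothing to the quarter even if its supply runs
  into it. Only under the one-unit-one-day reading does "74 doses over 3
  consecutive months" coincide with "80% temporal coverage", which is why
  the package adopts it.
* A chronic user of year $y$ is **incident** (a new user) when they were
  not a user on January 1 of $y-1$: no supply interval covers that date and
  they were not a chronic user of $y-1$. The second clause matters: a
  chronic user's refill gap can happen to straddle January 1, and a patient
  chronic in two consecutive years must never be counted as newly exposed
  in the second. A chronic user *is*, by definition, a user at their anchor.
* A chronic user of year $y$ **discontinues** when no oral dispensing is
  dated in November-December of $y$ (no more refills). Patients who died on
  or before October 31 mechanically discontinue; they stay in the
  numerator but are tallied separately so the yearly table can footnote
  them.
* Supply intervals merge into **episodes of use**; an uncovered run of at
  least `gap_days = 61` days (the length of a November-December "two
  months") ends an episode, and the next dispensing starts a new one.
  Resumption after such a gap is a new episode of chronic use.
* A patient dead before January 1 of year $y$ is not chronic for $y$,
  whatever their autumn dose count: vital status is part of being "a user
  on January 1".

Two further operationalizations are fixed by the anchor design: age is
completed years at January 1 of the cohort year, and the "adult" inclusion
(`>= 18`) plus the parenteral-only exclusion are applied before
classification, with parenteral rows of retained patients removed from
coverage and DDD accounting (hospital parenteral doses say nothing about
community refill behaviour).

### Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| `threshold` | 0.80 | coverage fraction | 74 doses / 92 days; the published operating point |
| `gap_days` | 61 | days | "two consecutive months" = Nov 1 - Dec 31 |
| `sensitivity_thresholds` | 0.75, 0.80, 0.85 | coverage | dose cutoffs 69/74/79; the chronic count is provably non-increasing in the threshold |
| `decimals` | 1 | - | published rates print one decimal, half away from zero |

All windows are closed; a dispensing dated on October 1 or December 31
counts. Dose thresholds at arbitrary coverage are
`ceiling(threshold * n_days)` - integer dose counts cannot undershoot the
fraction - with a `round(, 9)` guard so binary representation error
(0.8 × 92 = 73.6000…01 in doubles) can never shift the cutoff.

## Derived quantities

`ppi_study()` aggregates the per-patient classification into the study's
published quantities: prevalent and incident cohort sizes, incidence and
prevalence rates over user-supplied general-population denominators,
discontinuation proportions (with the death tally), demographics (mean/SD,
median/IQR of age - midpoint median, inclusive type-7 quartiles, IQR
reported as the single width $q_3 - q_1$ - and sex shares), the annual
defined-daily-dose totals `units × dosage_mg / ddd_mg` with the cohort
median, the dispensation mix by INN × dosage as event shares, and
prescriber attribution: the *initiation* prescriber is that of the first
dispensing anywhere in the loaded data (the data span is the lookback - a
documented limitation, not a look-back window), and the *first renewal*
prescriber is that of the earliest dispensing bearing a different
prescription id. Across-year trends in proportions use the Cochran-Armitage
score test (`stats::prop.trend.test`) with calendar years as scores; the
test is a standard tool, so it is called, not re-implemented, and the test
suite checks it against a Monte-Carlo permutation oracle.

DDD reference values are deliberately user-supplied. The bundled
`drug_reference.csv` carries plausible example maintenance-dose strengths
for the five oral PPIs so the simulator and examples run; it is not an
asserted transcription of the WHO ATC/DDD index and real analyses should
provide their own table.

Rounding is half away from zero everywhere, which reproduces published
one-decimal rates exactly (e.g. 19,551/156,721 → 12.5%). The two-decimal
discontinuation percentages printed in some regional reports are *not*
recoverable from their own printed counts under any single rounding rule
(19,551/156,721 = 12.4750% → 12.48 at two decimals); the pipeline therefore
reports both precisions and treats the one-decimal values as the
reproducible ones.

## The synthetic claims generator

`simulate_claims()` emulates the data-generating process the analysis
assumes, with planted ground truth:

* **Population**: ages normal (default mean 70, SD 15, truncated at 18 at
  the study start), 54.4% female, yearly mortality 3% - an elderly,
  slightly female-majority chronic-user pool. Each patient owns two RNG
  sub-streams derived from `(seed, patient index)`, so enlarging a cohort
  never perturbs already-generated patients.
* **Refill behaviour**: dispensings are boxes of mostly 28 (sometimes 14)
  units; inter-box gaps are geometric with mean
  $\mathrm{units}\,(1-c)/c$ for a per-patient adherence coverage
  $c \sim U(0.85, 0.98)$, truncated at 20 days so a refill delay can never
  split an episode by itself.
* **Chronic dynamics**: a non-chronic patient initiates at an anchor with
  probability `annual_new_chronic_probability` (first box in early October
  of the preceding year); each chronic patient-year discontinues with
  probability `annual_discontinuation_probability` (refills stop by late
  October); a discontinuer resumes with probability
  `resumption_probability` the following spring - a new episode, at least
  61 uncovered days later, counting as incident again two anchors on.
  Every planted chronic anchor is guaranteed its 74 in-window doses by an
  early-refill *top-up* step; labels in death years are derived from the
  truncated schedule, so generated data and labels agree by construction
  (and the test suite verifies the classifier recovers them exactly).
* **Noise**: a configurable fraction of patients are occasional users (at
  most two boxes in a quiet year - 56 units, structurally below the 74-dose
  bar), products are drawn i.i.d. per dispensing from the configured
  INN × dosage mix, prescriptions group 1-3 consecutive boxes, and
  prescribers are drawn per prescription from a GP-dominated mix.

The defaults mirror the study conditions of a French regional adult cohort
observed October 2015 - December 2020 (anchors 2016-2020, analysis years
2017-2020, with 2016 as burn-in so new-user status is always assessable).
No published description of dispensing cadence exists, so the box/gap model
above is an assumption - stated here once and not tuned. The generator
deliberately does **not** reproduce published table values (it is not
calibrated to them), does not model indication, co-prescription, the 2020
incident spike, or care-access disruptions; consequently, passing tests
show that the *pipeline arithmetic* is right under the stated assumptions,
not that real claims data behave this way.

Parameter-recovery experiments (planted discontinuation hazards 0.05,
0.125, 0.25 at 10,000 patients) disable mortality: deaths mechanically
create discontinuations - the published tables footnote them for the same
reason - so isolating the refill-behaviour parameter requires removing the
competing mechanism. Spec-level experiment sizes used throughout the tests
are 10,000 patients for statistical recovery checks and 200 randomized
mini-cohorts (up to 20 patients x 3 years) for exact day-grid oracle
equivalence.

## Numerical and degenerate-input choices

* Date arithmetic is integer day arithmetic on `Date`; no time zones.
* Episode merging breaks ties by dispensing date then units; output is
  invariant to input record order.
* `detect_discontinuation()` on a non-chronic patient-year is a contract
  violation (error), as is a parenteral record in `supply_interval()`.
* A year with no prevalent chronic patients has an undefined
  discontinuation proportion (error at the operation level; `NA` in the
  pipeline summary).
* Empty patient sets error in `demographics_summary()` and
  `median_annual_ddd()`; an empty renewal tally reports `NA` percentages.
* Flat proportions give trend statistic 0 and p = 1.
* Incident status is `NA` (not an error) at table level for anchors whose
  preceding January 1 lies before the data period.

## Reproducibility

`run_pipeline()` writes the complete report bundle (yearly summary, mix,
prescribers, chronic status, episodes, sensitivity, manifest) and is
byte-identical under a fixed config and seed; the manifest echoes the
configuration, seed, versions and row counts needed to reproduce a run.
The `inst/cli/ppicohort` script exposes the same stages as shell
subcommands.

## Known limitations

* The data span is the initiation lookback; patients first observed mid-span
  may be misclassified as initiators.
* Dose accounting is unit-based, not milligram-based; switching between
  PPIs is invisible to coverage (all PPIs pool), and "dose" equals one
  dispensed unit - if a source records doses as DDD equivalents the
  threshold semantics change.
* Chronic status is evaluated only at January 1 anchors with the fixed
  October-December trailing window, not as a rolling scan; mid-year
  initiation and cessation within a single year are visible only through
  episodes, not the chronic flags.
* The generator's cadence model is an assumption; its parameter defaults
  are plausible, not estimated.
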