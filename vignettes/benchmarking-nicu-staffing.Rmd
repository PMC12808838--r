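---
title: "Benchmarking acuity-adjusted nurse staffing in neonatal intensive care"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking acuity-adjusted nurse staffing in neonatal intensive care}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acuitybench)
```

## The problem

Neonatal intensive care units (NICUs) staff around the clock, but how many
registered nurses (RNs) a shift *needs* depends on who is in the cots.
Three-level dependency classifications grade each admitted infant-day as
intensive care (IC), high-dependency care (HDC) or special care (SC), and
staffing standards attach nurse-to-infant ratios of 1:1, 1:2 and 1:4 to those
categories. acuitybench implements that benchmark as a pipeline over three
tabular inputs — admission records, daily intervention reports, and staff
shift records — and reports, per unit and shift, the acuity-adjusted
recommended RN hours, the provided clinical RN hours, and their quotient, the
**RN provision ratio**. A ratio below 1.0 marks an understaffed shift.

## The model

For a unit-shift with infant-hours $h_{IC}, h_{HDC}, h_{SC}$ in the three
categories,

$$\text{recommended RN hours} = 1.0\,h_{IC} + 0.5\,h_{HDC} + 0.25\,h_{SC},$$

the hour-denominated form of the 1:1/1:2/1:4 ratios. Dividing by the window
duration gives a whole-shift RN count; dividing provided clinical RN hours
(bachelor-level RNs plus specialist RNs; nursing assistants never count) by
the recommendation gives the provision ratio.

### Care-days and shift windows

All accounting is anchored at **07:00**: a care-day runs 07:00–07:00, and
each care-day partitions into a day window (07:00–14:00, 7 h), an evening
window (14:00–21:00, 7 h) and a night window (21:00–07:00, 10 h) attributed
to the date it starts. Working on windows rather than raw rostered shifts
(which run roughly 07:00–15:30, 13:30–21:30 and 21:00–07:15 and overlap)
charges every hour to exactly one shift. Two conventions follow
automatically:

* an admission at, say, 03:00 belongs to the *previous* date's care-day and
  its hours before 07:00 are booked to that date's night shift;
* all intervals are half-open `[start, end)`, so a discharge at exactly
  14:00 contributes nothing to the evening window and the 24-hour partition
  is exact. The boundary semantics are a package choice; the benchmark
  definition does not dictate one, and half-open is the only option that
  makes the partition lossless.

Home-leave intervals subtract from presence in full. Whether an infant on
leave still books some nursing time is genuinely open; we subtract fully and
note that this slightly lowers recommended hours on leave days.

### Acuity classification

Each infant care-day is classified from its daily intervention flags by an
ordered rule table (first match wins, default SC), shipped as an editable
YAML document rather than hard-coded logic, because the full register-level
predicate list is an editable clinical judgement. The packaged default,
labelled *reconstructed*, encodes the three-level category definitions for
the six named register interventions: invasive/mechanical respiratory
support or a chest drain imply IC; non-invasive support or an umbilical line
imply HDC; parenteral nutrition without any respiratory support implies HDC
under the **adapted** scheme (the default) and IC under the original one.
That single toggle is the entire difference between the two schemes, so
switching it changes exactly the PN-without-respiratory-support days, always
toward IC under the original scheme. The adapted handling is deliberately
conservative: it avoids grading infants higher than their likely nursing
need and thereby avoids manufacturing falsely low provision ratios.

The adapted default table is severity-monotone: adding an intervention flag
to a day can never lower its category. The original scheme is inherently not
(adding non-invasive support to a PN-only day moves it IC→HDC), which is one
reason the adapted variant is the default. Every classified day records its
`matched_rule_id`, and run manifests carry the rule-file hash, so
classifications are auditable.

Days an admitted infant has no intervention record default to SC with a
warning and a count (configurable to a hard error) — again the conservative
direction. Intervention records outside any admission are always an error.

## Tunable parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| acuity weights | 1.0 / 0.5 / 0.25 | RN per infant | the 1:1/1:2/1:4 standard |
| window durations | 7 / 7 / 10 | hours | day/evening/night truncation |
| `adapted` | `TRUE` | — | PN-without-respiratory-support → HDC |
| `include_coordinator` | `FALSE` | — | coordinators are tracked separately |
| missing-day policy | SC + warning | — | conservative fallback |

Coordinator hours are accumulated in their own ledger column. Whether the
study-level benchmark should add a coordinator to the requirement or count
coordinator hours as provision is not settled; both switches exist
(`include_coordinator` in `benchmark_table()`) and both default to "no",
keeping the bedside benchmark pure.

## The synthetic-data generator

Real admission, register and roster extracts are hospital data and not
shippable, so the package carries a generator whose defaults *are* the study
conditions the analysis expects, with known ground truth at every stage:

* **Cohort** (`cohort_params()`): three units with Level-4/3/2 acuity
  profiles, 16 weeks, admission rates 7/12/16 per unit-week (≈560
  admissions); gestational-age strata 23–28/28–32/32–37/>37 weeks with
  probabilities 7.9/10.0/29.1/53.0%; log-normal length of stay matched to
  per-stratum mean (SD) 37.3 (29.5), 19.6 (15.3), 8.2 (6.7), 3.6 (3.5) days,
  truncated at 1 day (and capped at 180 days as a tail guard), with LOS
  counted as discharge date − admission date + 1. Admission time-of-day is
  uniform — no published arrival pattern exists to emulate, so the
  distribution is an explicit parameter rather than a guess.
* **Acuity dynamics**: a first-order Markov chain per care-day. Each unit
  uses a sticky chain $P_u = \alpha I + (1-\alpha)\mathbf{1}\pi_u'$ with
  persistence $\alpha = 0.6$, whose stationary law $\pi_u$ is exactly the
  unit's target case mix (42/47.7/10.3% for the Level-4-like unit,
  17.1/41.1/41.8% and 3.3/37.7/58.9% for the others). Admission-day acuity
  is drawn per GA stratum (more preterm ⇒ more IC). A first-order chain is
  the smallest model that reproduces day-to-day acuity fluctuation.
* **Interventions**: emitted as the *minimal* flag set implying the target
  category under the adapted rules (IC days get invasive support; HDC days
  parenteral nutrition and/or non-invasive support; SC days nothing
  qualifying), plus non-qualifying noise flags (phototherapy, tube feeding).
  Classification therefore round-trips to the ground truth with 100%
  agreement — by construction, which is the point: it makes the rule engine
  and everything downstream testable against a known answer.
* **Roster** (`roster_params()`): for each unit-shift the generator
  schedules clinical RN + specialist hours equal to
  `target_ratio × recommended hours`, quantised *up* to the 0.25 h
  scheduling quantum (real rosters are quarter-hour granular; rounding up
  means a roster calibrated at 1.0 is never pushed below 1.0 by rounding
  alone). Defaults: target ratio 0.76 with between-shift SD 0.22 (≈ an IQR
  of 0.30), RN share of staff hours 46.5% (SD 0.08), specialist share of RN
  hours 61/73/80% on day/evening/night shifts (SD 0.08), coordinators on
  85.4%/1.2%/0% of day/evening/night shifts, 5% nonclinical records and 5%
  agency flags. Records align to window boundaries — 7 h and 10 h blocks,
  merged 14 h day+evening shifts, sub-shift remainders — because the ratio
  is defined on windowed hours: any spill past a boundary would be charged
  to the neighbouring shift and break the calibration identity. An empty
  unit-shift (zero recommendation) still gets one baseline RN; its ratio is
  undefined and excluded from ratio summaries.

What the generator does **not** emulate: parent-support workload,
admission/discharge churn, transfers between units, staff identities
persisting across shifts, weekday/weekend census cycles, or the raw
07:00–15:30-style roster grid. Passing tests therefore demonstrate that the
pipeline's arithmetic, conventions and recovery behaviour are correct under
the stated statistical structure — not that any particular hospital is
staffed at these levels.

## Statistical summaries

Distributions are reported as mean (SD, normal-approximation 95% CI
$\bar x \pm 1.96\,s/\sqrt n$) and median (IQR = Q3 − Q1 with the linear
interpolation quantile convention — the most common default, fixed and
documented here because a single-number IQR is ambiguous otherwise).
Skill-mix proportions are computed per shift first, then summarised.

Two contrasts mirror the intended use: Kruskal–Wallis for specialist share
across shift types within a unit, and two-sided Mann–Whitney U for the
provision ratio between weekdays and weekends within a shift type — the
latter reported both pooled over units and per unit, since either reading of
"across units" is defensible. No multiplicity correction is applied; raw
p-values are reported at α = 0.05.

Numerical conventions for the tests: the Kruskal–Wallis statistic is the
tie-corrected H; with total n ≤ 10 the p-value comes from exhaustive
enumeration of all label assignments (the χ² approximation is unreliable
there — on three groups of two it can be off by >0.03), otherwise from the
χ² distribution with k − 1 degrees of freedom. Mann–Whitney uses the exact U
distribution when min(n) ≤ 8 with no ties, else the tie-corrected normal
approximation with continuity correction. Samples with no variation at all
are flagged degenerate and reported with statistic 0 (or U = n₁n₂/2) and
p = 1 rather than NaN.

## A worked run

```{r, eval = FALSE}
bundle <- simulate_study(cohort_params(n_weeks = 4, seed = 7),
                         roster_params(seed = 8))
acuity <- classify_cohort(bundle$interventions, default_ruleset(),
                          bundle$admissions)
ledgers <- build_ledgers(bundle$admissions, acuity, bundle$staffing,
                         bundle$windows)
bench <- benchmark_table(ledgers)
summarize_benchmark(bench)$headline
```

`run_demo(dir, seed)` wraps the same sequence, writes the fixture and all
report artefacts (CSV tables, a markdown report, three figures), and is
byte-deterministic given the seed.

## Problem sizes and numerical choices

The shipped tests run the generator at 1–5 weeks (126–315 shift windows) for
property checks and 16 weeks (1008 windows, ≈5,500 care-days) for the
end-to-end round trip; these sizes give stable medians (quantisation error
≤ 0.25 h per shift against recommendations of 20–70 h) while keeping a full
suite run around a minute. Interval arithmetic is exact to the second;
equality assertions on hours use tolerances of 1e-9 except where a
1-minute brute-force oracle defines the comparison (1/60 h). Overlapping
duplicate staff records are merged by interval union with a warning —
double-counting a person is never physically meaningful. Transfers are
separate admission records per unit; no cross-unit stitching is attempted.

## Known limitations

* The default rule table is a reconstruction from the six named register
  interventions; the register's remaining fields are supported by the
  vocabulary mechanism but carry no default rules. Both
  "mechanical" and "invasive" respiratory support flags are accepted and
  either implies IC, in case a source system treats them as distinct.
* Acuity is constant within a care-day; within-day deterioration books at
  the day's single category.
* The benchmark is acuity-only: unit layout, admission churn and parental
  support are outside the requirement model by design.
* Five-level dependency classifications are out of scope; the three-level
  scheme is the unit of analysis.
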