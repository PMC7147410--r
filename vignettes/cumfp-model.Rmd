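---
title: "A Markov cohort model of the cumulative false-positive rate in repeated screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort model of the cumulative false-positive rate in repeated screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cumfp)
```

## The question the model answers

A non-invasive colorectal-cancer screening test with specificity $s$ gives a
lesion-free participant a false-positive (FP) result with probability $1-s$
at each round. Screening programmes repeat the test every 1–3 years from
around age 50 to age 74, so the per-round risk compounds: the quantity of
interest is the *cumulative* number of persons who ever receive at least one
false positive (cumFP) by a given age, per 100 000 persons at age 50. A
false positive here means a positive test in a person free of colorectal
neoplasia — cancer *and* adenomas — at the time of the test, which is the
conservative reading (positives in adenoma carriers are not counted).

## Model structure and assumptions

The cohort model is deterministic (proportions, not simulated individuals)
with annual cycles and five states: alive and neoplasia-free without/with a
prior FP, alive with neoplasia without/with a prior FP, and dead. Its
assumptions:

* Only persons alive, neoplasia-free and never previously false-positive can
  contribute a *first* FP. The counter `cum_fp` records first FPs and is
  never decremented: a person who tests false-positive and later develops
  neoplasia or dies stays counted. (Counting FP prevalence among the living
  instead would give materially lower numbers and is not what a "cumulative
  number of persons" means.)
* Neoplasia is absorbing. Onset removes a person from the FP-eligible pool
  permanently; natural history beyond that (progression, detection,
  polypectomy) is deliberately out of scope because it cannot change cumFP
  under the definition above.
* Perfect adherence: everyone alive and eligible attends every round.
* Within a cycle the order is screening (at exact integer ages), then
  neoplasia incidence, then death. No half-cycle correction. The order is a
  modelling convention; it makes the engine's lesion-free occupancy at a
  screening instant equal $F(a_r)$ below, so engine and closed form agree
  exactly rather than to first order.
* Sequential tests are conditionally independent in the base case: the same
  $1-s$ applies at every round. The sensitivity variant lowers the FP
  probability by an absolute $\delta$ (default 0.01, i.e. one percentage
  point — $2\% \to 1\%$, not a relative 1%) from the second round onward.
  With perfect adherence, a lesion-free person with no prior FP at round $r$
  has exactly $r-1$ prior true negatives, so "after one or more true
  negatives" is implemented as "round index $\ge 2$" without tracking test
  histories. The percentage-point reading is the one consistent with the
  roughly 40% drop in cumFP it produces at $s = 0.98$; a relative 1% change
  would be invisible.

## The closed form and why survivorship is sufficient

Let $F(a)$ be the fraction of the age-50 cohort alive and neoplasia-free at
age $a$, $a_r$ the screening ages and $p_r$ the per-round FP probabilities.
A person lesion-free at round $r$ has attended all previous rounds
lesion-free, so their chance of a *first* FP at round $r$ is
$w_r = p_r \prod_{j<r}(1-p_j)$, and

$$\mathrm{cumFP}(a) = 100\,000 \sum_{r:\,a_r \le a} F(a_r)\, w_r .$$

Two consequences drive the package design:

1. **cumFP depends on mortality and incidence only through $F$.** Two
   schedule pairs with the same per-age product $(1-i(a))(1-q(a))$ give
   identical cumFP; the split is unidentifiable from cumFP and irrelevant to
   it. The tests assert this invariance on the engine directly.
2. **At fixed shape, cumFP is proportional to the scale $f_{50}=F(50)$.**
   So one printed cumFP value identifies the scale exactly.

The closed form is exact under the engine's cycle-order convention, so the
engine-vs-oracle property tests use a numerical-noise tolerance (1e−9), not
a modelling tolerance: any disagreement is a bug.

## Calibration

The empirical inputs behind the original analysis — age-specific neoplasia
incidence from the colonoscopy arm of a screening trial and Dutch national
life-table mortality — are not available as data. Rather than guess both
schedules, the package calibrates the sufficient statistic directly:

* **Shape:** $F$ declines linearly over ages 50–74 with
  $F(74)/F(50) = 0.54$ (about 54% of lesion-free 50-year-olds are still
  lesion-free at 74). Linearity is the simplest shape consistent with the
  published outputs; it is an inference from reproduction quality, not an
  observed curve, which is why the reproduction tolerances below are 1.5–3%
  rather than numerical noise.
* **Scale:** $f_{50}$ is fitted so the biennial / specificity-0.98 /
  start-50 programme reaches an age-74 cumFP of 15 102 per 100 000. By
  proportionality this is a one-line division by the unit-scale cumFP:

```{r calibration}
curve <- calibrate_survivorship(ratio_74 = 0.54,
                                anchor_scenario = screening_scenario(50, 74, 2, 0.98),
                                anchor_value = 15102)
attr(curve, "f50")
```

With this single calibration, every other published scenario value is a
prediction, not a fit — the reproduction suite checks the base-case age-74
values to within 1.5% and the dependence-variant values to within 3% (the
linear-$F$ approximation degrades slightly when the round weights shift
toward early rounds).

For engine runs a concrete schedule pair is still needed.
`make_gompertz_mortality()` supplies a synthetic Gompertz life table,
$q(a) = \min(1, A e^{Ba})$ with defaults $A = 3\times10^{-5}$, $B = 0.09$
per year — about 0.0027 at age 50 and 0.023 at 74, realistic for a
contemporary Western-European population — and
`derive_incidence_from_survivorship()` inverts the recursion
$F(a+1) = F(a)(1-i(a))(1-q(a))$ to find the incidence that, combined with
that mortality, reproduces $F$ exactly (round-trip tested to 1e−12). By the
invariance above, nothing downstream depends on the Gompertz choice.

Scenarios that start screening at 54 or 58 are run from age 50 against the
same reference cohort (`run_from = 50`), so all table columns share the
per-100 000-at-50 denominator. Simulating ages below 50 would change
nothing: earlier ages affect cumFP only through $f_{50}$.

## Tunable parameters

| Parameter | Meaning | Default | Units |
|---|---|---|---|
| `specificity` | per-test specificity $s$ | 0.98 / 0.95 / 0.92 in the catalogue | fraction |
| `interval` | years between rounds | 1 / 2 / 3 | years |
| `start_age`, `stop_age` | first / last eligible screening age | 50 (54, 58) and 74 | years |
| `dependence_reduction` | absolute FP-probability drop after a true negative | 0 (base), 0.01 (variant) | probability |
| `ratio_74` | $F(74)/F(50)$ | 0.54 | fraction |
| `anchor_value` | age-74 cumFP pinning $f_{50}$ | 15 102 | per 100 000 |

Both the start and the stop age are test-eligible: the last round is the
largest grid age $\le 74$, which is age 74 itself for all three intervals —
consistent with age-74 values that differ by interval. The scenario
catalogue (`scenario_catalogue()`) is the 3 × 3 grid of interval ×
specificity at start 50 plus the two later-start variants: 11 scenarios,
each with a `dependence_reduction = 0.01` twin on request.

## What the synthetic data emulate — and what they do not

`make_gompertz_mortality()` and the derived incidence schedule emulate the
*aggregate attrition* of a real screening cohort, not its fine structure.
Real incidence is noisy in age and not exactly what a linear $F$ implies;
real life tables have cohort effects; adherence is imperfect; specificity
varies with age, sex and haemoglobin cut-off. Passing tests therefore show
that the mechanics (engine, closed form, calibration, inversion) are exact
and that a two-anchor linear survivorship reproduces the published scenario
table — they do not validate the model against individual-level screening
data. The one external touchpoint is the five-round FIT-programme check
(`zorzi_check()`), where the calibrated model's 88.3 per 1000 falls just
below the observed 91–98 per 1000.

```{r tables}
tab <- cumfp_table(curve)
round_half_up(unlist(tab[tab$age == 74, -1]))
zorzi_check(curve)
```

## Numerical choices

* Real-valued occupancies throughout; cells are rounded (half-up, matching
  the integer presentation convention) only when tables are serialized.
* Conservation of cohort mass is asserted at 1e−9 relative at every cycle.
* Derived incidence values within 1e−9 outside $[0,1]$ are clipped
  (floating-point guard at curve endpoints); larger violations — mortality
  alone exceeding the attrition $F$ demands — raise an error naming the age.
* Schedule CSVs (`age,probability`) require consecutive integer ages; a gap
  is an error, never silently interpolated.
* cumFP-column inversion (`invert_cumfp_to_survivorship`) is defined only at
  screening ages; interpolating $F$ between rounds would invent data. A zero
  first-FP round weight (e.g. $\delta = 1-s$) makes $F$ unidentifiable at
  that round and errors.
* The external five-round check collapses the programme's 50–54 entry-age
  band to its midpoint, age 52, and reports per 1000 of the age-50 cohort
  scale.

## Problem sizes

Everything here is desk-scale: one engine run is 25 annual cycles over five
states, a full 11-scenario table takes well under a second, and the
property suites use tens of randomized schedule/scenario draws under fixed
seeds. These sizes are ample because the model is deterministic — there is
no Monte Carlo error to average away.

## Known limitations

* The incidence/mortality split is unidentifiable from cumFP; the bundled
  Gompertz mortality is a synthetic stand-in, and only the product
  $(1-i)(1-q)$ is calibrated.
* Linearity of $F$ is an assumption; a spline or Gompertz-shaped
  survivorship is a straightforward extension but unconstrained by the two
  available anchors.
* No imperfect adherence, no test sensitivity (true positives do not enter
  cumFP), no sex stratification, no colonoscopy-capacity modelling.
* The dependence variant is a single uniform percentage-point reduction; the
  empirical pattern of conditional dependence over many rounds is unknown.
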