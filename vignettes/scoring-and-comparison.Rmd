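---
title: "Scoring child diet quality: the HEI-2005 and RC-DQI, and how their schemes compare"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring child diet quality: the HEI-2005 and RC-DQI, and how their schemes compare}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(childdqi)
```

## The measurement problem

Composite diet quality indexes summarise a diet's compliance with
food-group and nutrient recommendations in a single score. For children
this is delicate: children eat less food than adults but need a higher
nutrient density, so an index can either control for energy by scoring
densities (the HEI-2005 approach) or compare absolute intakes to
age-specific targets (the RC-DQI approach). Both are defensible; they
are not interchangeable. Because five recommendations — dairy, fruit,
vegetables, total grains, whole grains — appear in both indexes, the
two scoring philosophies can be compared on identical dietary data,
and this package implements that comparison end to end.

The unit of analysis is a child with two 24-hour dietary recalls.
Usual intake is the field-wise arithmetic mean of the two days;
children with fewer than two days are excluded by the loaders (a
`keep_single_day` flag retains them for sensitivity runs). No
usual-intake distribution correction (NCI/ISU style) is applied: the
comparison scores the same sample twice under two rules, so
within-person variance inflates both sides identically and no
individual-level inference is made. Survey weights are likewise not
applied; a `weights` column is accepted and ignored with a warning.

## HEI-2005

Twelve components, 100 points. Every food-group component is first
expressed as a density per 1000 kcal, `d = 1000 * amount / energy`;
saturated fat and SoFAAS (calories from solid fats, alcohol and added
sugars) are already percent-of-energy and pass through unchanged.

* Adequacy (more is better): total fruit (5 pts at ≥ 0.8 c/1000 kcal),
  whole fruit (5 at 0.4), total vegetables (5 at 1.1), dark-green/orange
  vegetables and legumes (5 at 0.4), total grains (5 at 3.0 oz), whole
  grains (5 at 1.5 oz), milk (10 at 1.3 c), meat and beans (10 at
  2.5 oz), oils (10 at 12 g). Score `m * min(1, d / d_star)`: zero if
  and only if intake is zero.
* Moderation (less is better): saturated fat (10 pts at ≤ 7% of energy,
  0 at ≥ 15%), sodium (10 at ≤ 0.7 g/1000 kcal, 0 at ≥ 2.0), SoFAAS
  (20 at ≤ 20% of energy, 0 at ≥ 50%). Between the two printed anchors
  the score is a single linear segment.

The single-segment proration is a deliberate reading of the index's
"linear fashion" rule with only the two printed anchors. The official
HEI-2005 technical implementation inserts an intermediate breakpoint
for some moderation components (e.g. 8 points at 10% saturated fat); a
`hei_proration` mode is reserved for that piecewise variant but not
implemented, and the package scores the published two-anchor rule.
Density scoring makes all HEI food-group components invariant to
proportional rescaling of amounts and energy, a property the test
suite checks directly.

## RC-DQI

Thirteen components, 90 points, for ages 2–18.

* Five food groups (total grains 5 pts, whole grains 5, fruit 10,
  vegetables 10, dairy 10) score `m * min(1, intake / target(age))`
  against age-indexed daily targets. Only a child who consumed none of
  a group scores zero; partial consumption is deducted proportionally.
* Macronutrients: added sugar (10 pts, cap at 10% of energy), total fat
  (2.5, acceptable range 30–40% of energy at ages 2–3 and 25–35% at
  4–18), linoleic acid (2.5, range 5–10%), α-linolenic acid (2.5, range
  0.6–1.2%), DHA+EPA (2.5, cap at 10% of α-linolenic intake). Range
  components score full inside the band, decay as `value/lo` below and
  `hi/value` above; cap components decay as `cap/value` above the cap.
* Excess fruit juice: 10 pts within the pediatric age-appropriate limit
  (6 fl oz/day at ages 2–6, 12 at 7–18), ratio decay beyond it.
* Iron: categorical — 0 points at or below the age band's EAR-derived
  threshold, 10 at or above the RDA-derived one, 5 between. The four
  threshold columns map to the DRI age bands 2–3, 4–8, 9–13, 14–18.
* TV/energy: `(TV score + energy score)/2`. TV earns 10 points at
  ≤ 2 h/day; unreported viewing is imputed by age band (2–6 y: 2 h,
  7–14 y: 4 h, 15–18 y: 3.5 h). Energy earns 10 points within ±10% of
  the age-indexed EER.

Two printed variants of the target table are shipped and selectable
(`variant = "table_b"` / `"table_c"`); they differ in the food-group
targets from age 4 up, in the upper iron bands, and in the per-age EER
(table c's energy pattern is substantially higher for teenagers). The
source material does not state which variant produced its published
numbers, so both are first-class and the choice is a logged, explicit
argument; `table_b` is the default as the variant printed first and the
one whose EER matches a sedentary energy pattern.

### Decisions where the printed rules underdetermine the scheme

* **Energy score outside the EER window.** Read literally, the printed
  over/underconsumption formulas give 0 points at the window edge where
  the window itself gives 10 — a discontinuity. The default
  (`eer_formula = "proportional"`) anchors ratio decay at the window
  edges: `10 * energy / (0.9 * EER)` below, `10 * (1.1 * EER) / energy`
  above. It is continuous, monotone away from the window, and zero only
  at zero intake, consistent with the index's proportional-deduction
  philosophy. The literal formula remains available
  (`eer_formula = "literal"`, clamped to [0, 10]) so the ambiguity is
  auditable.
* **TV above 2 h.** The printed rule fixes only the 10-point threshold;
  the package decays as `10 * 2 / hours`, continuous at 2 h and never
  negative.
* **Cap components** decay as `m * cap/value` rather than hitting zero
  at a finite bound, preserving "zero only at the extreme" and
  monotonicity for a continuous score.
* **Linoleic acid's** printed "≤5–10%" is scored as the range
  [5%, 10%]; the stray "≤" is treated as typographical.
* **Iron band gaps.** The printed categorical bands leave small gaps
  for continuous intakes (e.g. between 5.7 and 5.8 mg); the
  implementation uses "≤ EAR bound → 0, ≥ RDA bound → 10, else 5",
  which partitions the line and preserves every printed anchor.
* **Sex** is accepted in the profiles but does not enter target lookup:
  the printed tables index by age only.

## The five-component comparison

Both indexes' dairy scores (max 10) and the RC-DQI fruit and vegetable
scores (max 10) are divided by two, bringing all five comparable
components to 0–5; grain components are unchanged. The subscore is
their sum, 0–25. Keeping dairy at 10 points would have doubled its
weight in the subscore, hence the halving on both sides.

Three diagnostics are computed for the total sample and for each age,
ethnic and income stratum:

1. **Within-index correlations** — pairwise Pearson r between the five
   components of one index, flagged at the 0.05 and 0.01 levels with a
   two-sided t-test on n − 2 degrees of freedom. No multiple-testing
   correction is applied (none is applied in the analyses this mirrors).
   A component constant within a stratum has undefined correlations,
   reported as missing rather than zero.
2. **Between-index correlations** — the full 5 × 5 matrix of HEI
   components against RC-DQI components over the same children. These
   are signed Pearson r values (a published caption labels the analogous
   table "r-square", but it contains negative entries, so the signed
   coefficient is the only consistent reading).
3. **Distribution classes** — per component and for the subscore, the
   proportions of children at the minimum (0), strictly between, and at
   the maximum (5, or 25). Boundary membership is exact to a 1e-9
   tolerance; scores are kept at full floating precision throughout and
   rounded only in reports. This is the dichotomization diagnostic: a
   scheme that piles children onto 0 or 5 differentiates less than one
   that spreads them between the extremes.

Income strata follow the food-assistance eligibility cut points on the
poverty-income ratio (low ≤ 1.85, high ≥ 3.5, medium otherwise — the
printed cut points leave the intervals (1.85, 1.86) and [3.4, 3.5)
unassigned for continuous PIR, and the implementation closes them as
stated, preserving both printed endpoints). Ethnicity is recoded to
Hispanic/other, non-Hispanic white and non-Hispanic black; ages 2–5,
6–11 and 12–18 form the age groups.

## The synthetic generator

`simulate_children()` emulates the *structure* of a national two-day
recall sample of children, not its population values:

* Ages are drawn in the three groups in proportion 1405 : 1586 : 2945,
  the composition of the study sample the pipeline is designed for, and
  `preset_study_shape()` fixes N = 5,936.
* Food-group amounts are zero-inflated gamma. A child is a
  never-consumer of a group with probability `p_zero` (zero on both
  days); consumers receive a gamma personal mean density whose log-mean
  is shifted by `lambda * z` for a shared latent diet-quality factor
  `z ~ N(0, 1)`. The latent factor induces the weak positive
  inter-component correlations (roughly 0.05–0.3 after scoring) that
  characterise real dietary data; day-level amounts then multiply in
  mean-one lognormal noise with a 0.35 day-to-day CV, the order of
  within-person variation seen in recall data.
* Zero-inflation defaults are moderate for episodically consumed
  groups (whole grains 0.22 within grain consumers, juice 0.30,
  dark-green/orange vegetables 0.35, fruit 0.10) and near zero for
  staples — the zero-inflated-gamma form is the standard model for
  episodically consumed foods.
* Energy is lognormal around the age-indexed EER (σ = 0.20), so energy
  scores are realistically centred; density-basis amounts scale with
  the day's energy.
* Percent-of-energy fields are truncated normal with means near
  children's typical intakes (e.g. saturated fat 11%, SoFAAS 35%,
  added sugar 16%); moderation-type quantities load negatively on `z`.
* PIR is gamma truncated at 5.0; TV hours are gamma (mean 2.6 h) with
  an 8% missingness rate exercising the imputation path.

Zero-inflation is applied at the child level deliberately: the HEI
minimum class for a component is exactly the set of children with zero
two-day intake, so the configured `p_zero` is recoverable from the
pipeline output — the parameter-recovery tests check that at
n = 5,000 within binomial sampling error, and that with all `p_zero`
set to 0 both indexes' minimum-class proportions are exactly zero.

What the generator does **not** reproduce: real food-pattern
correlations beyond a single latent factor (fruit juice is generated
independently of total fruit rather than as a component of it),
seasonal and weekday effects, measurement error of recalls, survey
design (clustering, oversampling, weights), and the actual NHANES
intake distributions. Passing tests on synthetic data therefore
demonstrate that the scoring and comparison machinery is correct and
that structural claims (e.g. "the RC-DQI places more children between
the extremes than the HEI for most components") emerge under realistic
intake shapes — they do not certify population-level numbers, which
require the external survey and food-equivalents data.

## Numerical choices and degenerate inputs

* All scoring is vectorised double arithmetic; component scores are
  exact at the printed anchors (the proration ratios at the standards
  are exact binary fractions in the tested cases) and verified against
  an independent piecewise-linear interpolation oracle to 1e-12.
* Zero energy is rejected (densities undefined); zero targets and caps
  are rejected.
* Ages are completed integer years; fractional ages are floored with a
  warning. PIR above 5 is truncated with a warning.
* Boundary classification in distribution classes uses a 1e-9 absolute
  tolerance so that a score of 5 reached by exact arithmetic counts as
  the maximum, while prorated scores arbitrarily close to it do not.
* Constant score vectors propagate as missing correlations; strata
  with fewer than 3 children refuse to correlate rather than returning
  spurious coefficients.

Routine checks in the test suite run at n between 120 and 1,500
children; the parameter-recovery checks use n = 5,000 and the
study-shaped run N = 5,936 — the full pipeline at that size takes a
few seconds, so these sizes are comfortable for routine re-runs.

## Known limitations

* The HEI moderation components implement the published two-anchor
  linear rule, not the technical report's piecewise variant; totals for
  diets in the affected intermediate region can differ by a few points
  from the official SAS/Stata implementations.
* Legume allocation between the vegetable and meat/bean groups is
  assumed done upstream: the package consumes pre-disaggregated
  MyPyramid-style equivalents and does not parse survey files or food
  codes.
* The RC-DQI fruit component uses total (juice-inclusive) fruit, with
  juice overconsumption handled by its own excess-juice component;
  analyses that require juice-free fruit would need a different input
  mapping.
* Scores are group-level instruments. Neither index was designed to
  rank individuals, and the package's reports are population summaries
  accordingly.
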