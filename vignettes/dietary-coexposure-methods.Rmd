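---
title: "Estimating dietary co-exposure to food contaminants: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating dietary co-exposure to food contaminants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietexposome)
```

## The problem and the model

Dietary risk assessment traditionally evaluates one contaminant at a time
against its own health-based guidance value. But a diet delivers a *mixture*:
every meal carries traces of heavy metals, PAHs, pesticide residues,
mycotoxins and heterocyclic aromatic amines simultaneously. `dietexposome`
estimates that mixture deterministically. The pipeline has four stages, each
behind its own function surface:

1. **Occurrence harmonisation** (`read_occurrence()`, `apply_exclusions()`,
   `harmonize_occurrence()`). Study-level measurements of a contaminant in a
   food are filtered and standardised to µg of contaminant per kg of food.
2. **Weighted estimation** (`estimate_concentrations()`). Each food ×
   contaminant pair is summarised by a sample-size-weighted mean and weighted
   25th/50th/75th percentiles.
3. **Exposure scenarios** (`build_scenario()`). A dietary model (grams of
   each food per day) converts concentration percentiles into daily burdens.
4. **Guidance screening** (`screen_scenario()`). Burdens are compared with
   per-person daily amounts derived from TWI/TDI/ADI values, or with
   margin-of-exposure thresholds for benchmark-dose reference points.

The central modelling assumption is the **comonotonic percentile stack**: a
"p25 scenario" places *every* food × contaminant pair at its own 25th
percentile simultaneously. Real concentrations are not perfectly correlated
across foods and analytes, so the p75 scenario in particular is a
conservative co-exposure construction — useful as a worst-case mixture
recipe, not as a probabilistic exposure estimate. A two-dimensional
Monte-Carlo exposure model is deliberately out of scope.

## Occurrence records and their filters

A record is one study-level measurement: food, cooking state, contaminant,
central value (mean or median) with its unit and wet/dry basis, sample size
`n`, censoring status with LOD/LOQ, and a sample flag. Three exclusion rules
are applied before estimation:

- records from artificially contaminated samples, feed samples, or animal
  experiments are dropped (`artificial`, `feed`, `animal_model`);
- records reporting only a minimum or maximum are dropped (`minmax_only`),
  because an extremum with unknown position in the distribution cannot be
  pooled without bias;
- dry-weight-basis records are dropped except for the cereal group (wheat,
  maize, rice), where dry reporting is conventional and the moisture
  difference is modest; retained dry-basis cereal values are used as-is,
  with no moisture correction.

Left-censored records contribute `LOD/√2` (below detection) or `LOQ/√2`
(below quantification). Substitution — rather than, say, maximum-likelihood
fitting of a censored lognormal — keeps the estimator free of distributional
assumptions; the √2 divisor is the standard compromise between the 0 and
LOD bounds. The substituted value never exceeds its threshold, which the
test suite asserts as an invariant.

Cooking-state variants (raw/grilled/fried/…) of a food are pooled under one
food key by default, because dietary models specify foods, not preparations;
`harmonize_occurrence(stratify_cooking = TRUE)` keeps them separate for
analyses of cooking effects.

### Controlled vocabularies

Foods (16: four animal-based, twelve plant-based) and contaminants (73: 4
heavy metals, 18 PAHs, 10 pesticides, 29 mycotoxins, 12 HAAs) live in
packaged lookup tables; parsing is case-insensitive with a strict-mode
switch, because literature-derived tables have naming drift. The class
counts are fixed design targets; where the analyte panel underlying the
published class sizes is not fully enumerated in public summaries, the
vocabulary is completed with field-standard analytes (benzo[j]fluoranthene
and 5-methylchrysene among the PAHs; HT-2 toxin among the mycotoxins;
Trp-P-1 and Trp-P-2 among the HAAs). Users with their own panels can ignore
strict mode or extend the tables.

## The weighted percentile

The field convention for pooling occurrence data weights each study value by
its sample size. Percentile conventions, however, are rarely stated, and
different choices disagree noticeably at the small per-pair record counts
typical of curated occurrence tables. `weighted_percentile()` therefore
isolates one documented convention:

- sort values, **pool exact ties** (summing their weights);
- place pooled value *i* at the midpoint of its normalised cumulative-weight
  interval, `p_i = (c_{i-1} + c_i)/2` (weighted Hazen convention);
- interpolate linearly between the `(p_i, v_i)` points; clamp to the
  smallest/largest value outside `[p_1, p_n]`.

This convention has three properties worth the choice:

1. **Weight-scale invariance** — multiplying all weights by a constant
   changes nothing, so "sample size" can be relative.
2. **Expansion consistency** — for integer weights it agrees *exactly* with
   applying the same convention to the multiset in which each value is
   repeated weight-many times. Tie pooling is what makes this identity
   exact; without it, interpolation spans differ between the weighted and
   expanded forms. The test suite checks this identity against an
   independent brute-force expansion oracle on 1,000 randomised instances.
3. **Reduction to the classical case** — with unit weights and distinct
   values it equals the ordinary midpoint-convention percentile
   (`quantile(type = 5)`), which has lower small-sample bias than the
   step-function conventions.

A non-interpolating alternative (`method = "step"`, the left-continuous
inverse of the weighted CDF) is available for users who require percentiles
to be attained values.

Numerical notes: a single (pooled) value returns itself for any `q`;
`q` is restricted to the open interval (0, 1); tie pooling uses exact
floating-point equality, so values that are equal only "in exact
arithmetic" (for instance the same censoring threshold reported through
different units, which round-trips differently at the last bit) may remain
distinct — the effect on estimates is at machine precision.

Within a pair, a median-type record substitutes for a mean only when its
study contributes no mean-type record; medians from studies without means
enter the pool alongside other studies' means. Records with absent `n`
receive weight 1 — such records document an observation but not its
precision, and weight 1 is the conservative floor.

### Congener aggregation and proxy foods

Cumulative indicators (ENNs, EgTs, ATs) are formed by summing member
estimates percentile-wise within each food. Summing percentiles assumes the
members co-vary (comonotonicity); this matches the cumulative-indicator
convention for congener families that share producers and commodities, and
it is the only choice consistent with the scenario construction above.
Absent members contribute zero. Bread and pasta, sparsely measured
themselves, inherit the estimates of maize and wheat respectively; direct
estimates, where they exist, are never overwritten, and provenance is
recorded on every row (`direct`, `congener_sum`, `proxy_from_*`).

## Dietary models

The two packaged models follow the EAT-Lancet reference-diet food groups,
with representative foods chosen so that both deliver 1580 g/day and closely
matched energy. Masses and energies are stored per item exactly as
published; the per-item energies sum to 2339 kcal/day (omnivorous) and
2305 kcal/day (vegetarian), each 1 kcal above the published rounded totals
(2338 and 2304) because items and totals were rounded independently at the
source. The package reports the item sums and documents the ±1 kcal
discrepancy rather than altering published items to force agreement.

`validate_ranges()` checks group totals against the reference ranges with
*inclusive* bounds, since reference diets legitimately sit exactly on a
bound (whole grains at 600 g/day in the omnivorous model). The vegetarian
model's other-protein group (beans + peanuts, 280 g/day) exceeds its
250 g/day reference ceiling; the validator reports `above`, as it should —
range validation describes the model, it does not gate it. Nutrient
profiling beyond per-item energy bookkeeping is out of scope: contaminant
burden needs masses, and energy is kept only to check model comparability.

## Scenarios and screening

`build_scenario()` computes burdens, class totals, the global burden as the
sum *of the class totals* (so the partition identity
`Σ class_totals = global` holds exactly, not merely to rounding), and the
global burden per kg of diet. Report tables round for display — one decimal
at ≥100 µg, two in [1, 100), three below 1 µg — while full-precision values
are always written alongside.

Screening conventions, chosen once and documented:

- TWI values (per week) are divided by exactly 7; all conversions are linear
  in body weight (default 70 kg). One published daily mercury figure is
  arithmetically inconsistent with its own weekly value (280/7 = 40, not
  16); the package computes 40 µg/day and does not reproduce the
  inconsistency.
- Exposure exactly equal to a reference amount is `within`; regulatory
  phrasing ("below the threshold") implies strict inequality for concern.
- BMDL entries *with* a margin-of-exposure threshold (ochratoxin A: 200
  non-neoplastic, 10,000 neoplastic) are screened by
  `MOE = BMDL/(exposure/bw)`; MOE exactly at the threshold is low concern,
  and zero exposure (no computable MOE) is reported as `NA` with a
  low-concern flag. BMDL entries *without* a threshold (inorganic arsenic,
  lead) act as direct per-person reference points — exposure is compared
  with BMDL × bw — mirroring how such reference points are used in
  practice when no MOE-of-low-concern has been set.
- Duplicate registry rows are rejected per contaminant + guidance type +
  endpoint, which permits lead's two BMDL01 entries (different endpoints)
  while catching genuine conflicts.
- The ochratoxin A "331–1015 µg/day" span is BMDL × bw, not a tolerable
  intake; it is derivable from the registry (`to_daily_amount()`) but not
  stored as a TDI.

## The synthetic generator

`generate_occurrence()` emulates the statistical structure the estimator
assumes: per-pair study-level concentrations drawn from a lognormal
(geometric mean `gm`, geometric SD `gsd`; occurrence data are non-negative
and right-skewed — a gamma alternative with matched mean and variance is
available), uniform study sample sizes, censoring imposed by thresholding
draws at fixed quantiles of the generating distribution (so the expected
censored fraction equals `loq_quantile`, split between below-LOD and
below-LOQ at `lod_quantile`), reporting units drawn from a configurable
mix, a configurable fraction of dry-basis cereal records, and small
fractions of median-only, min/max-only, flagged and missing-`n` records to
exercise the filters. Defaults (3–10 studies per pair, 3–30 samples per
study, 20% censoring, ~4% excluded records) reflect the scale and
messiness of a curated literature-mined occurrence table, where a pair
typically rests on a handful of studies of modest size.

What the generator does *not* emulate — and what passing tests therefore do
not demonstrate about real data: between-study heterogeneity beyond
lognormal sampling (no country or year effects), correlation between a
study's sample size and its reported level (publication bias), correlated
co-occurrence of contaminants within samples, or non-lognormal tails.
Parameter-recovery results on synthetic data validate the estimator's
arithmetic, not the realism of any particular occurrence database.

Determinism: all draws derive from the single `seed`; the same seed yields
byte-identical CSV output. `generate_fixture_suite()` additionally freezes
an expected-estimates table computed by an independent expansion-oracle
implementation, re-derived from the occurrence CSV *as parsed* so the
shipped fixture and its reference outputs are exactly consistent.

## Problem sizes and tolerances in the test suite

The suite favours sizes that make statistical checks sharp but quick: the
expansion-oracle identity is exercised on 1,000 random instances of ≤ 8
values (it is an exact identity, tolerance 10⁻¹²); censoring calibration
uses ≥ 10,000 records against a ±0.02 binomial band; end-to-end median
recovery uses one pair with 200 clean lognormal studies (GM 10 µg/kg,
GSD 2, no censoring, seed 1) against a 5% band — at this size the Monte
Carlo standard error of a weighted median is ≈ 6–7% of the true value, so
the band is tight relative to the estimator's sampling noise and the check
is seed-pinned rather than distribution-free. Smaller recovery checks (50
studies) use correspondingly wide 40% bands.

## Known limitations

- Percentile stacking overstates co-occurrence at the upper percentiles by
  construction (comonotonicity), and understates nothing.
- Substitution at LOD/√2 biases low-percentile estimates of heavily
  censored pairs upward relative to censored-likelihood methods.
- Proxy-food fill-in copies distributions wholesale; processing effects
  (milling, baking) on contaminant levels in bread/pasta are ignored.
- Screening is per contaminant; no mixture metric (hazard index, combined
  margin of exposure) is computed.
- Guidance values evolve; the packaged registry is a snapshot, and
  `read_hbgv()` accepts user-maintained registries.
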