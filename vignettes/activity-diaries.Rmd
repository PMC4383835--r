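---
title: "Scoring and simulating 15-minute activity diaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and simulating 15-minute activity diaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metdiary)
```

## The diary model

A diary day is an ordered sequence of 96 fifteen-minute slots; slot $i$
(0-based) covers the half-open clock interval $[15i, 15(i+1))$ minutes after
midnight. The day is anchored at 00:00 purely by convention — no computed
metric depends on where the day starts, only on how many slots hold each
activity, so any consistent anchor is equivalent. Each slot holds one
activity code that resolves through a *compendium* to

* a MET intensity $m \in [0.9, 18]$ (multiples of resting metabolic rate;
  0.9 is the conventional sleeping value),
* one of five categories — `household`, `transportation`, `work`,
  `leisure_sports`, or `uncategorized` — and a free subcategory tag.

The fifth category exists because a day's four behaviour categories sum to
roughly 850–870 minutes in population tables of this kind, leaving about
570 minutes of sleep, meals and personal care that must count toward total
MET but never toward a behaviour-category total.

Each participant records one weekday and one weekend day. Per-day metrics
(24-hour mean MET, MET-hours, MVPA, category/subcategory minutes and
MET-hours) are combined as a typical day with weights $5/7$ and $2/7$. The
weighting commutes with every per-day metric because all metrics are linear
in per-slot contributions, which the test suite exploits: an independent
brute-force sum over all 192 weighted slots must agree with the vectorised
scorer to $10^{-12}$.

Two conventions deserve flagging because the field's descriptions are often
ambiguous:

* **MVPA sums the full MET value** of qualifying slots (threshold
  *inclusive* at exactly 3.0 MET), not the net value $m - 1$. This keeps
  MVPA in the same MET-hours units as the total and matches the magnitudes
  reported by diary studies; it is an assumption, stated here because
  published methods sections rarely say which variant they used.
* A 10-minute activity is necessarily recorded as a 15-minute slot. This
  granularity bias is inherent to the instrument (and a known reason diary
  MVPA runs higher than accelerometer MVPA); no correction is attempted.

Completeness is strict: a record is analysable only if *all* 96 slots of
*both* days are filled. One missing slot invalidates the participant; no
imputation. This is the strictest reading of "complete two-day dataset" and
reproduces the exclusion-percentage arithmetic of the survey this package
models (excluded/total × 100, reported to 2 decimals).

## The compendium fixture

The surveys this package emulates used a menu of 91 activities in the four
categories; the actual menu and its MET assignments were never published.
The packaged fixture (`default_compendium()`) is therefore a **synthetic
stand-in**: 91 activities whose labels and MET values follow Ainsworth
compendium conventions, plus four uncategorized activities (sleep 0.9,
personal care 2.0, eating 1.5, bathing 1.3), covering every subcategory the
scoring decomposition and the MVPA regression use. Users can replace it
with any CSV of the same five columns. One deliberate choice: car commuting
is scored at 2.0 MET (the older compendium's "driving" value) rather than
the 1.3 of passive sitting, so that regional transportation MET-hours have
realistic magnitude in car-dependent strata.

## Statistical conventions

* SD uses the $n-1$ denominator throughout; medians and quartiles use
  linear interpolation between order statistics (`quantile()` type 7), so
  results are bit-reproducible.
* ANCOVA adjusted means are model predictions averaged over the observed
  covariate profile of the analysis sample with the group forced to each
  level — the *proportional-weights* least-squares-means convention (equal
  to `emmeans` with `weights = "proportional"`, which a test verifies).
* Categorical covariates (7 occupation levels, 5 income bands) are
  reference-coded against their first level; rows with any missing value in
  the used columns are dropped listwise and counted, which is how surveys
  of this kind end up with slightly different denominators per model.
* Tukey HSD uses the Tukey–Kramer unequal-$n$ rule; all tests are
  two-sided at $\alpha = .05$; no multiplicity correction is applied across
  outcome families beyond Tukey within a factor, mirroring common practice
  in the field.
* `anova_from_summary()` recomputes a one-way ANOVA from printed group
  means/SDs/sizes ($SS_B$ from means, $MS_W$ pooled from SDs). It is
  algebraically identical to the raw-data ANOVA and exists so published
  tables can be checked without raw data; agreement with a printed $F$ is
  limited by the table's rounding (a printed 7.26 can only be recovered to
  within roughly ±0.2 from one-decimal means and SDs).

## The synthetic cohort generator

The generator exists because the survey data this pipeline was designed for
are not deposited. It is *schedule-level*: it never draws summary
statistics directly. Each participant gets covariates from stratified
categorical distributions (area, sex by area, age band by area, occupation
by sex, income by area, marriage, exercise habit, anthropometry), then a
latent profile — worker type, job intensity type
(sedentary/standing/physical), commute mode, child at home — and finally
two full 96-slot days assembled from activity *blocks*: a sleep block
wrapping midnight, morning routine, commute → work (with
sitting/standing/vigorous/walking segments and a lunch slot) → commute,
household blocks, errand/outing trips, an optional sport session, dinner,
bath, and sedentary leisure filling the remainder. Blocks are drawn in
whole slots from clamped rounded normals; if requested blocks exceed the
awake window they are truncated proportionally with a warning (about 1% of
days under the default configuration). Because scored marginals emerge only
through the scorer, generator plus scorer form a genuine round trip.

Randomness is reproducible at participant granularity: each participant
has a private substream seeded from the config seed, so enlarging the
cohort reproduces earlier participants byte-for-byte, and generation
restores the caller's RNG state.

**Calibration.** The packaged configuration (`paper2012-v1`, seed
20120712, $n = 2046$, areas 46.4/21.1/32.5%) was fitted by coarse manual
search on schedule parameters only — job-type mixes by sex and area,
commute mode probabilities and one-way durations, household block sizes,
sleep and sport parameters — against published population marginals for
this survey design: overall mean weighted MET 1.60 and median weighted
MVPA 7.92 MET-hours/day; per-area totals 37.9/38.8/39.1 MET-hours/day;
per-area transportation and walking-commute patterns; rural-men mean MVPA
10.8. `calibration_report()` regenerates and tabulates these with absolute
deviations. At the packaged seed all targets sit within tolerance and both
regional orderings (total activity urban < urban-rural < rural;
transportation highest in urban areas) hold. The urban/rural contrast is
driven by mechanism, not by drawn offsets: urban strata commute by transit
and on foot to long sitting jobs; rural strata drive to jobs with more
standing and physical work — so adjusting for demographics leaves the area
contrast in place, as it should.

**What the generator does not emulate.** Within-person week-to-week
variance (each participant is two days, exactly as the instrument
collects); seasonality and weather; correlation between occupation and
area beyond the margins (independence within strata is assumed);
recall/self-report bias; and any demographic structure beyond the published
margins. Passing calibration therefore shows the *pipeline* is faithful and
the population summaries are attainable under a plausible behavioural
mechanism — it does not validate the generator as a model of real Japanese
time use.

## Numerical and degenerate-input choices

* Work-segment slot counts use largest-remainder rounding so segments tile
  the work block exactly.
* A single-observation `distribution_summary()` reports SD 0 with an
  explicit `sd_undefined` flag rather than `NA`, so downstream table code
  never propagates missingness silently.
* An empty cohort filters to an empty cohort with a zero-count report;
  scoring an empty cohort returns a zero-row table.
* Collinear model matrices are refused with the offending column named;
  empty factor cells abort the interaction model.
* Incomplete diaries abort scoring with the offending participant ids
  listed, rather than being dropped silently — dropping is the
  responsibility of the explicit `filter_complete()` step.

## Problem sizes used by the test suite

The suite exercises the scoring oracle on 100 random two-day diaries, the
calibration round trip on the full $n = 2046$ default cohort, and the
statistical-size check on 500 regenerated null cohorts of $n = 300$ (all
area strata given identical parameters), confirming type-I error within
$0.05 \pm 0.02$ for the one-way ANOVA, the ANCOVA and the sex × area
interaction test. These sizes were chosen so the whole suite runs in a few
minutes on a laptop while keeping binomial noise on the size estimates
below the tolerance being asserted.

## Known limitations

* The compendium is a structural stand-in; absolute subcategory MET-hours
  depend on its MET assignments, though all relative comparisons the
  pipeline makes are insensitive to small reassignments.
* The MVPA regression's very high $R^2$ (~0.99 on synthetic cohorts) is a
  property of the generator — nearly all above-threshold activity falls in
  the ten modelled behaviours — and should be read as an upper bound on
  what real diaries would show.
* Listwise covariate deletion approximates, but cannot exactly reproduce,
  the per-model denominators of any particular published analysis, because
  the exact covariate coding behind printed degrees of freedom is not
  recoverable.
* p-value display follows the leading-dot journal style in rendered tables;
  CSV artifacts always carry raw floats.
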