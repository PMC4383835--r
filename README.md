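# metdiary

Scoring, simulation and analysis of 15-minute physical activity diaries in R.

Web-based activity-record surveys ask participants to fill a 24-hour grid of
96 fifteen-minute slots with a preset activity, once for a weekday and once
for a weekend day. Each activity maps, through a compendium, to an intensity
in metabolic equivalents (MET — multiples of resting metabolic rate) and to
one of four behaviour categories (household, transportation, work,
leisure/sports; sleep and personal care stay outside the four categories).
`metdiary` is for epidemiologists and exercise scientists who work with such
diaries: it validates and scores them, compares cohorts across residential
strata, and — because raw survey data of this kind are rarely deposited —
ships a seeded, schedule-level synthetic cohort generator whose scored
marginals match published population summaries, so the whole pipeline can be
exercised and tested without any download.

## The quantities computed

With `met_i` the MET intensity of slot `i` of one day (`i = 0..95`, slot `i`
covering `[15 i, 15 (i+1))` minutes after midnight):

- **24-hour mean MET** `= (Σ_i met_i) / 96`, and **MET-hours/day**
  `= Σ_i met_i · 0.25 = 24 ×` mean MET;
- **MVPA** (moderate-to-vigorous physical activity, MET-hours/day)
  `= Σ_{i : met_i ≥ 3} met_i · 0.25` — the threshold is inclusive and the
  full MET of qualifying slots is summed;
- every metric is computed per day and combined across the two recorded
  days as a "typical day": `(5 × weekday + 2 × weekend) / 7`;
- category and subcategory decompositions in minutes and MET-hours
  (e.g. walking/transit/car commuting; sitting/standing/vigorous/walking
  work).

Cohort statistics follow the standard epidemiological toolkit: one-way
ANOVA (also recomputable from printed means/SDs/ns via
`anova_from_summary()`), one-way ANCOVA with least-squares adjusted means,
a two-way sex × area interaction ANCOVA, Tukey HSD (Tukey–Kramer for
unequal n), Pearson chi-square, and OLS regression with standardized
coefficients (β).

## Worked example

```r
library(metdiary)
comp   <- default_compendium()                 # 91 + 4 activities
cfg    <- default_config()                     # calibrated generator, seed 20120712
cohort <- generate_cohort(cfg)                 # 2046 two-day diaries
scores <- score_cohort(filter_complete(cohort)$cohort, comp)

distribution_summary(scores, "mean_met")
#> <summary_stats> mean_met (n=2046)
#>   mean 1.586 (SD 0.187)  median 1.528  IQR 1.45-1.69

distribution_summary(scores, "mvpa_met_hours")
#> <summary_stats> mvpa_met_hours (n=2046)
#>   mean 9.965 (SD 7.073)  median 7.457  IQR 4.99-13.70

one_way_ancova(scores, "met_hours", "area",
               c("age", "sex", "occupation", "income_band", "marital_status"))
#> <ancova_result> F(2,2030) = 12.686, p = <.001 (n = 2046, 0 dropped)
#>   adjusted means:
#>     rural          38.673
#>     urban          37.603
#>     urban_rural    38.063
```

The cohort mean 24-hour MET of 1.586 says the average synthetic participant
spends the day at ~1.6 times resting metabolic rate; the adjusted means show
the urban stratum with the lowest total activity (37.6 MET-hours/day) and
the rural stratum the highest (38.7), a difference that survives adjustment
for age, sex, occupation, income and marriage. MVPA is strongly
right-skewed (mean 10.0 vs median 7.5 MET-hours/day): most activity above
3 MET is concentrated in participants with standing or physical jobs.
Regressing MVPA on ten behaviour subcategories,

```r
standardized_regression(scores, "mvpa_met_hours", paste0("sub_meth_",
  c("work_standing", "work_vigorous", "sport_exercise", "cooking", "cleaning",
    "cycling_transport", "car_wash_gardening", "childcare", "commute_walk",
    "work_walking")))
#> <regression_result> R^2 = 0.987, SEE = 0.793, p = <.001, n = 2046
#>   standardized betas (|beta| descending):
#>     sub_meth_work_standing       +0.583
#>     sub_meth_work_vigorous       +0.404
#>     sub_meth_sport_exercise      +0.340
#>     ...
```

standing work carries the largest standardized coefficient: it is the
behaviour whose between-person variation contributes most to MVPA.

A full pipeline run (`generate → validate → score → analyze → report`)
writes CSV tables, JSON metadata and a manifest:

```r
run_pipeline(system.file("extdata", "config_paper2012.json", package = "metdiary"),
             out_dir = "out")
```

or from a shell via the thin wrapper `inst/cli/metdiary.R`:

```sh
Rscript inst/cli/metdiary.R all --out out --seed 20120712
```

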