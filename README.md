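# itsagree

Tools for studying whether interruption effect estimates computed from
**digitally extracted** interrupted time series (ITS) graph data agree with
estimates computed from the **original** data.

Systematic reviews that meta-analyse ITS studies usually need each study's
raw series, which is rarely published — but a graph almost always is, and
plot-extraction software can recover the plotted coordinates. The question
is whether the extraction errors that inevitably occur (points read between
tick marks, mis-calibrated axes, missed points, two points rounded onto one
time unit) propagate into the level- and slope-change estimates a
meta-analysis would use. `itsagree` implements the full study design as
reusable, tested code, including a synthetic generator for both the series
and the error processes, so every stage runs at any scale with no external
data.

## The model

Each series follows segmented linear regression with lag-1 autocorrelated
errors:

```
Y_t = β0 + β1·t + β2·D_t + β3·(t − TI)·D_t + ε_t,    ε_t = ρ·ε_{t−1} + w_t
```

with `D_t = 0` before the interruption time `TI` and 1 at and after it, and
`w_t ~ N(0, σ_w²)`. The effects of interest are the immediate level change
`β2` and slope change `β3`. Fitting is by REML allowing lag-1
autocorrelation (ρ profiled numerically, variance analytically), with a
group-level fallback: if REML fails to converge for any dataset describing
a series, all datasets of that series are refitted by OLS.

Agreement between data sources is summarised the way method-comparison
studies do: effects standardised by the provided series' outcome range,
Bland–Altman mean differences with 95% limits of agreement
(mean ± 1.96 SD), geometric-mean ratios of standard errors, confidence
intervals rescaled so the comparator spans [−0.5, 0.5], and concordance of
p-value significance categories.

## A worked example

```r
library(itsagree)

st <- run_study(study_config("simulate", n_series = 43, seed = 1))
st
#> ITS digitization agreement study: 43 series analyzed (0 failed), policy reml_with_ols_fallback
#>   42 series groups fitted with REML(AR1), 1 with OLS fallback
#>   largest LoA half-width vs provided: 0.0224 (level_change, provided vs e2)

subset(st$agreement, effect == "level_change" & grepl("provided", comparison),
       select = c(comparison, n_series, mean_diff, loa_low, loa_high, gm_se_ratio))
#>       comparison n_series mean_diff loa_low loa_high gm_se_ratio
#> 1 provided vs e1       43 -0.000198 -0.0034   0.0030       1.000
#> 2 provided vs e2       43 -0.002014 -0.0244   0.0204       1.004
#> 3 provided vs e3       43  0.000940 -0.0104   0.0123       1.000
#> 4 provided vs e4       43 -0.001197 -0.0186   0.0162       0.982
```

Read: across 43 simulated series digitized by four simulated extractors of
increasing sloppiness, the mean difference in range-standardised level
change between each extractor and the truth is at most 0.002 (on a 0–1
scale), the widest 95% limits of agreement are about ±0.02, and estimated
standard errors agree within about 2% on the geometric mean — digitization
error of realistic magnitude barely moves the interruption effect
estimates. `st$error_summary` holds the per-extractor calibration table
(standardised intercepts/slopes, important-error counts, missingness);
`st$concordance` the p-value category agreement; `st$ci_widths` the scaled
confidence-interval comparisons.

The lower-level surface is fully exposed: `simulate_true_series()`,
`apply_extraction_error()`, `read_xy_csv()`, `snap_to_grid()`,
`resolve_interruption()`, `build_design()`, `fit_ols()`, `fit_reml_ar1()`,
`fit_series_group()`, `pair_points()`, `calibration_regression()`,
`flag_important_error()`, `bland_altman()`, `se_ratio_stats()`,
`ci_ratio_scaled()`, `categorize_p()`, `concordance()`. A thin CLI wrapper
lives at `inst/cli/itsagree` (verbs `simulate` and `run`).

See `vignettes/its-digitization-agreement.Rmd` for the methods account:
model assumptions, the interruption-placement rules and their trade-offs,
what the error generator does and does not emulate, and numerical choices.

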