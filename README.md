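# coralforage

Use-versus-availability analysis of territorial, coral-feeding reef fish.

Field studies of obligate corallivores (e.g. butterflyfish that feed almost
exclusively on live hard-coral tissue) typically collect three tables: a
point-intercept photoquadrat survey of the substrate inside each feeding
territory, timed bite counts on each coral prey category for a focal pair,
and territory metadata (site class, perimeter). `coralforage` turns those
tables — or fully synthetic equivalents with known ground truth — into the
standard selectivity and space-use analysis, for reef-fish ecologists and
for anyone teaching or stress-testing resource-selection methods.

## What it computes

**Availability.** Live coral cover per territory and the composition of the
seven coral prey categories as fractions *of live coral*, pooled to a site
availability vector `p` by summing point counts.

**Dietary selectivity.** With `u_ij` the bite count of unit `j` on category
`i`, `b_j` its total and `E(u_ij) = b_j p_i` the expectation under
proportional use, the log-likelihood chi-square statistic

    chi2_L2 = 2 * sum_j sum_i u_ij * ln( u_ij / E(u_ij) )

is referred to a chi-square distribution with `n (I - 1)` df. Larger values
mean stronger specialisation.

**Selection ratios.** The Manly resource selection function
`w_i = mean_j (u_ij / b_j) / p_i` with between-unit standard errors and
Bonferroni-corrected simultaneous 95% confidence intervals; `w > 1` with the
whole interval above 1 is a preference, below 1 an avoidance.

**Territory size and feeding rate.** Least-squares power law
`perimeter = a * cover^b` fitted on log10–log10 scale, Spearman rank
correlations (exact p for small untied samples), per-individual feeding
rates, and a pooled-variance t / variance-ratio F comparison of cover
between site classes with Lilliefors normality checks.

**Synthetic surveys.** `synthetic_config()` / `generate_survey()` emulate
the full study design (8 low + 6 intermediate + 9 high-cover territories,
500 points and one focal pair with 10 observation periods each, a declining
size–cover power law) with every true parameter recorded, and
`recovery_experiment()` replays generation + analysis to measure bias,
RMSE, CI coverage, test calibration and power.

## A worked example

```r
library(coralforage)
res <- run_analysis(list(synthetic = list(seed = 42)))
res
```

```
Dietary selectivity and prey preferences
site             n    chi2_L2        P    Acropora Pocillopora     Porites      Fungia     Galaxea   Montipora  OtherCoral
low              8        281  1.3e-34        0.97        2.14        1.15        1.14        1.34        0.66        0.52
intermediate     6        173  8.4e-20        1.04        2.10        0.93        1.09        0.88        1.28        0.39
high             9        532    1e-79        0.94        4.18        0.62        1.50        0.73        1.25        0.15

Live cover, low vs high sites: 13.23 +/- 2.00% (n=8) vs 51.36 +/- 2.40% (n=9)
  pooled t = -12.05, df = 15, p = 4.1e-09; F = 0.62, p = 0.539

Territory size vs cover: y = 536.15 x^-0.803, r2(log10) = 0.814, F(1,21) = 91.79, p = 4.08e-09
Spearman cover_vs_size: rho = -0.909, n = 23, p = 1.95e-09
Spearman cover_vs_rate: rho = -0.071, n = 23, p = 0.748
Spearman rate_vs_size: rho = 0.127, n = 23, p = 0.563
```

Reading the table: selectivity is significant everywhere (`chi2_L2` vs
chi-square with `n(I-1)` df), strongest at high cover. Pocillopora is taken
at ~4x its availability at high cover (preference) while the dominant
Acropora is grazed slightly below availability; at low cover the same
preferences are visibly relaxed. Cover differs sharply between site classes
(t = −12.05, df = 15), territories shrink with cover as a power law with a
negative exponent, and feeding rate shows no monotone relationship to cover
— the classic optimal-foraging pattern.

Per-site detail lives in `res$rsf$high` (ratios, SEs, intervals,
classifications), `res$selectivity`, `res$profiles`, `res$territory_stats`;
`autoplot(res$rsf$high)` and `autoplot(res$power_fit)` draw the standard
figures, and `tidy()` / `glance()` methods cover the fitted objects.
`run_simulation_study()` wraps the replicated recovery experiment. See the
vignette (`vignettes/foraging-selectivity.Rmd`) for the model, its
assumptions and the generator's design.

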