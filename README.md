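# svpower

Simulation-based experimental design for single-cell time-course
proteomics.

Mass-spectrometry measurement of a single cell destroys it, so a
time-course experiment never measures the same cell twice: every time
point is a different cell, and the change observed between points mixes
genuine temporal dynamics with cell-to-cell variability. Before
committing instrument time, a researcher planning such an experiment
needs to know how many cells to spread across the time domain to detect
a trend of a given size against a given level of heterogeneity — and how
to split a fixed cell budget between denser time courses and more
replicates. `svpower` answers these questions by Monte-Carlo simulation,
the time-course analogue of a power analysis.

## The model and the statistic

Each simulated cell has a pseudotime `t ~ Uniform(0, 1)` and one protein
abundance

```
y = s * t + b + e,        e ~ Normal(0, v)
```

with slope `s` (the effect size over the unit time course), intercept
`b` (default 1) and noise standard deviation `v` (biological plus
technical variability). From a large population (default 10,000 cells) a
subsample of `n` cells stands for one experiment. The subsample is
smoothed onto a 200-point pseudotime grid with a Gaussian kernel
(bandwidth 0.1), and the interpolated trajectory is classified by the
**area between curves (ABC)** — the mean absolute distance between two
curves on the grid:

* a truly changing protein is *detected* when its trajectory is closer
  to the generative line than to a flat null line (`ABC_true <
  ABC_null`);
* a truly flat protein is a *false positive* when its trajectory is
  closer to a sloped comparator than to the flat truth.

Repeating this over 1000 subsamples and 10 independently re-simulated
populations yields true-positive (TP) and false-positive (FP) rates with
Monte-Carlo error bars. Because the classifier is built from kernel
averages and absolute differences, the rates depend on `(s, v)` only
through the scale-free ratio **S/V = s / v**, which makes the results
portable across datasets regardless of their quantification scale.

For real data, where the generative line is unknown, `estimate_sv()`
estimates S/V as `|OLS slope| / sd(residuals)`, and the package
quantifies how precise that estimate is at a given sample size and what
fraction of proteins an estimated-S/V cutoff would retain.
`replicate_rate()` / `n_of_k_rate()` turn per-course rates into
multi-replicate detection rates (`p^x`, or a binomial tail for
n-of-k rules), and `evaluate_budget()` compares budget allocations.

## Worked example

```r
library(svpower)

# TP rate for S/V = 2 with 16 cells across the time course
est <- estimate_accuracy(population_spec(slope = 1, noise_sd = 0.5),
                         n_sample = 16, seed = 1)
glance(est)
#> # A tibble: 1 × 9
#>   rate_kind  rate  spread n_subsamples n_repeats slope noise_sd    sv n_sample
#>   <chr>     <dbl>   <dbl>        <int>     <int> <dbl>    <dbl> <dbl>    <int>
#> 1 accuracy  0.823 0.00640         1000        10     1      0.5     2       16
```

About 82% of 16-cell experiments on an S/V = 2 protein correctly call it
changing; the spread (0.006) is the standard deviation across the 10
simulation repeats. Sweeping the ratio over two of its realisations and
two sample sizes:

```r
tab <- sv_sweep(sv_realizations(2, slopes = c(1, 2)),
                n_samples = c(16, 25), seed = 1)
sv_summary(tab)
#> # A tibble: 4 × 7
#>   rate_kind    sv n_sample realization_sd  spread   rate n_realizations
#>   <chr>     <dbl>    <int>          <dbl>   <dbl>  <dbl>          <int>
#> 1 accuracy      2       16       0.00453  0.0142  0.825               2
#> 2 accuracy      2       25       0.000919 0.0162  0.889               2
#> 3 fp_rate       2       16       0.00226  0.0129  0.127               2
#> 4 fp_rate       2       25       0.000212 0.00886 0.0760              2
```

Going from 16 to 25 cells lifts TP from 0.82 to 0.89 and drops FP from
0.13 to 0.08; the tiny `realization_sd` shows the two different
`(slope, noise)` realisations of S/V = 2 agree, i.e. the rates are scale
free. With a 50-cell budget, two replicates of 25 cells versus three of
16 (`all_of_k` detection):

```r
evaluate_budget(50, list(c(25, 2), c(16, 3)), tab, sv = 2)
#>   option per_course_tp per_course_fp overall_tp  overall_fp
#> 1   25x2       0.88895       0.07595  0.7902321 0.005768403
#> 2   16x3       0.82500       0.12690  0.5615156 0.002043548
```

The denser option wins on overall TP; the extra replicate wins on
overall FP — the classic design trade-off, now with numbers.

`autoplot()` methods draw the rate curves, estimator-error densities and
retention bars; `svpower_cli` (installed at
`system.file("scripts", "svpower", package = "svpower")`) exposes every
step as `simulate` / `power` / `sv` / `design` / `cohort` subcommands
with seeded, manifest-logged CSV outputs.

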