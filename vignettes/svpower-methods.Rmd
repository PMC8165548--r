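---
title: "Methods: simulation-based design for single-cell time courses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation-based design for single-cell time courses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svpower)
```

## The generative model

Destructive single-cell measurement means a time course is a collection
of cells, each observed once at one position along a biological
transition. `svpower` models one protein in such an experiment with the
simplest trajectory that captures a monotone transition:

$$y_i = s\,t_i + b + \varepsilon_i, \qquad t_i \sim \mathrm{U}(0, 1),
\qquad \varepsilon_i \sim \mathcal{N}(0, v^2).$$

Pseudotime is abstract and bounded: 0 is the start of the transition, 1
the end. Cells are independent; the noise term absorbs biological
heterogeneity and technical variability without distinguishing them —
for design purposes only their combined magnitude matters. A population
(default 10,000 cells) stands for the biology available to the
experiment; a subsample of $n$ cells, drawn uniformly without
replacement, stands for one experiment. Sampling is without replacement
because a measured cell is destroyed.

Parameters and defaults:

| parameter | meaning | default |
|---|---|---|
| `slope` ($s$) | abundance change over the unit time course | — |
| `noise_sd` ($v$) | SD of cell-to-cell noise, same units as abundance | — |
| `intercept` ($b$) | abundance at $t = 0$ | 1 |
| `n_cells` | population size | 10,000 |
| `n_sample` ($n$) | cells measured per time course | — |

Only the ratio $S/V = s/v$ matters for detection (see below), so the
absolute units of abundance are irrelevant; raw intensities and
log-transformed, zero-centred data are covered alike.

## Trajectory interpolation

A subsample is turned into a dense trajectory by Gaussian-kernel
weighted averaging (Nadaraya–Watson) on an equally spaced grid:

$$\hat{y}(g_k) = \frac{\sum_i y_i\, w_{ik}}{\sum_i w_{ik}},
\qquad w_{ik} = \exp\!\left(-\frac{(t_i - g_k)^2}{2h^2}\right),$$

with 200 grid points on $[0, 1]$ and bandwidth $h = 0.1$ by default —
the conventional settings for pseudotime interpolation of this kind.
The operator is exact for constant data, bounded by the sample's range,
and exactly shift- and scale-equivariant, which is what ultimately makes
the detection rates scale free. No boundary correction is applied: the
edge bias of kernel averaging (trajectories are pulled toward the
interior mean near $t = 0$ and $t = 1$) affects every Monte-Carlo arm
identically, so comparisons between arms are unaffected.

## The area-between-curves decision rule

Two trajectories on a shared grid are compared by the mean absolute
difference of their values (`area_between()`), a discrete area between
curves normalised by the span of the grid. Classification is a
two-reference contest:

* **TP runs** (changing population, $s \neq 0$): the subsample is called
  *changing* when its trajectory is strictly closer to the generative
  line than to a flat null line.
* **FP runs** (flat population, $s = 0$): the subsample is falsely
  called *changing* when its trajectory is strictly closer to a sloped
  comparator line than to the flat truth.

Exact ties go to *non-changing* — conservative toward the null, and
relevant only on measure-zero events (or the fully degenerate
noise-free flat case).

**Anchoring the references.** Where to put the flat null line, and the
comparator's height, is a genuine design choice. `svpower` anchors both
at the *population's* mean abundance level — the generative line's value
at the midpoint of the time range — rather than at each subsample's own
mean (`null_anchor`/`comparator_anchor = "subsample"` restores the
latter). The population anchor keeps the null line fixed across
subsamples, so a subsample whose mean is displaced by noise is not
handed a null line conveniently recentred onto it; with the subsample
anchor the null tracks the sample and wins more of the contests,
depressing TP rates noticeably at low S/V (by roughly 14 percentage
points at S/V = 1 with 16 cells) and raising FP rates. The comparator in
FP runs is likewise centred on the population level
(`anchor_mode = "center_at_mean"`), so the false-positive contest is
about *shape*, not offset: a comparator pinned at an offset the data
never visit would make false positives nearly impossible and hide the
real risk of over-calling dynamics at small $n$. `reference_line()` also
offers `intercept_at_zero` anchoring for users supplying their own
references.

In TP runs the truth is the known generative line — the simulator is its
own oracle. Applying `classify_subsample()` to real data therefore
requires the caller to supply a reference trajectory from prior
knowledge; the package makes no attempt to infer one.

## Monte-Carlo protocol

Each rate is estimated from `n_subsamples = 1000` subsamples per
population, repeated `n_repeats = 10` times with a freshly simulated
population per repeat; the reported rate is the mean over repeats and
the spread its standard deviation. Re-drawing the population per repeat
(rather than only the subsamples) propagates population-level
Monte-Carlo error into the error bars rather than hiding it. All
randomness flows from one master seed per engine call: child seeds for
repeats and sweep cells are drawn up front inside a single seeded scope
(`withr::with_seed`), so identical calls reproduce identical rates and
parallel cells never share a stream.

## Scale freeness and the S/V ratio

Multiplying $s$ and $v$ by the same factor $k$ rescales abundances
affinely about the intercept; the kernel average is affine-equivariant
and the ABC contest compares absolute differences, so every verdict is
unchanged in exact arithmetic (floating-point rounding can flip an
occasional near-tie). Rates therefore depend on $(s, v)$ only through
$S/V$. `sv_realizations()` expands a ratio into several concrete
$(s, v)$ pairs (default slopes 0.5, 0.75, 1, 1.5, 2, 3) and
`sv_sweep()` keeps per-realisation rows so the collapse is itself
testable; `sv_summary()` pools them.

## Estimating S/V without an oracle

On real data, S/V must be estimated. `estimate_sv()` fits OLS of
abundance on time and reports $|\hat{s}| / \hat{v}$ with $\hat{v}$ the
standard deviation of the residuals. Choices worth stating:

* the residual spread uses the $n-1$ sample-SD denominator; the $n-2$
  regression convention is available (`residual_denominator = "n-2"`,
  a <4% difference at $n = 30$);
* the magnitude $|\hat{s}|$ is used so that noise-driven negative slopes
  under a flat population count symmetrically toward retention;
* a residual spread at the level of float rounding (below
  $10^{-12}$ of the data scale) is treated as an exact fit and the
  ratio flagged `Inf` rather than returning an astronomically large
  finite number;
* the estimator is exactly scale free, so the $(s, v)$ realisation of a
  given true S/V does not matter — a property the test suite asserts.

`sv_error_distribution()` reports the distribution of
$S/V_\text{true} - S/V_\text{est}$ across subsampling events (error SD
roughly $\propto 1/\sqrt{n}$), and `filter_retention()` simulates
filtering events at an estimated-S/V cutoff, using 1000-cell populations
by default — retention is a screening question asked of smaller cohorts,
and the extra population-level variability at 1000 cells is part of the
answer.

## Replicates and budgets

Per-course rates combine across $k$ independent replicate time courses
as $p^k$ when detection in every replicate is required, or as the
binomial upper tail $\sum_{j \ge n} \binom{k}{j} p^j (1-p)^{k-j}$ for
at-least-$n$-of-$k$ rules; both apply the same formula to TP and FP
rates. `evaluate_budget()` looks per-course rates up from a sweep table
*exactly* — no interpolation between table cells, a deliberate guard
against silently trusting rates the simulation never produced. Replicate
means an independent repeat of the whole time-course sampling; no
within-replicate correlation is modelled.

## Two-group cohort summaries

To place real data on the S/V landscape, `effect_table()` reduces a
two-group protein-by-cell matrix (log-scale abundances) to per-protein
fold change — the absolute difference of group means — and within-group
variation, the sample SD of a designated reference group (an asymmetry
kept on purpose: the reference group is the biology whose variability
one trusts). Scaling the between-state transition to a unit pseudotime
makes `fold_change / within_group_sd` an S/V proxy. Missing values,
pervasive in single-cell proteomics, are ignored per protein with a
`min_obs` threshold (default 3 per group, dropped proteins counted and
messaged) — the simplest defensible policy, chosen over imputation,
which would manufacture variance structure the simulation does not
model. Values are assumed already log-transformed and normalised;
normalisation is out of scope. `synth_two_group_matrix()` generates
matrices of this shape with known effects, spreads and
missing-completely-at-random masking, and carries the truth as an
attribute so parameter recovery is testable without any external
download.

## Numerical and interface choices

* Ties in the ABC contest → non-changing (above).
* Grids are equally spaced; `area_between()` refuses mismatched grids
  rather than resampling silently.
* CSV serialisation writes doubles with 17 significant digits and reads
  them back through base `strtod`, so populations and trajectories
  round-trip bit exactly.
* The CLI resolves flags over YAML config over defaults and writes every
  run's resolved parameters and seed to `manifest.json`; identical
  manifests reproduce identical CSVs.

## What the simulation does and does not establish

The generator emulates: destructive uniform sampling of a transition,
linear trends, Gaussian cell-to-cell noise, and (in the cohort module)
log-scale two-group matrices with MCAR missingness. It does not emulate
nonlinear or cyclical trajectories (transient responses, circadian
patterns), non-Gaussian or heteroscedastic noise, correlated proteins,
batch effects, or informative missingness. Passing tests show the
machinery is correct under the stated model, not that real experiments
obey it; the rates are design-stage guidance, not guarantees.

Known behavioural edges: at very small samples ($n \approx 7$) the
kernel trajectory of even a noise-free sloped sample can be flattened
enough by clustered sampling and edge bias to fall closer to the flat
null, so noise-free accuracy is exactly 1 only from about 16 cells —
consistent with the general finding that fewer than ~16 cells per time
course is a fragile design. FP is exactly 0 at zero noise for any $n$.

## Problem sizes used by the tests

The acceptance-level checks run the full protocol (10,000-cell
populations, 1000 subsamples × 10 repeats; 1000-cell populations for
retention). Property-style checks (monotonicity in $n$ and in noise,
scale invariance) use 400–500 subsamples and 4–5 repeats, and cohort
recovery uses 200–300 proteins at 50–60 cells per group — sizes chosen
so Monte-Carlo spread is small against the asserted effects while the
whole suite stays quick on a laptop.
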