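---
title: "Elution-order prediction by QSRR with multi-objective optimization: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Elution-order prediction by QSRR with multi-objective optimization: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsrrmoo)
```

## The model

`qsrrmoo` works with linear quantitative structure–retention relationships
(QSRRs): the gradient retention time of an analyte, in minutes, is modelled
as an affine function of K molecular descriptors,

$$ t_R = \alpha_0 + \alpha_1 x_1 + \dots + \alpha_K x_K + \varepsilon . $$

The descriptors are *inputs* — typically computed elsewhere (quantum
chemistry, group additivity, clogP predictors) — and arrive as named columns
of a CSV table together with an analyte identifier and the observed
retention time. Two schema presets mirror the case studies the method was
developed for: small organic molecules described by the total dipole moment,
the most negative atomic charge, and the solvent-accessible surface area
(`config_cs1()`); and synthetic peptides described by the log of the summed
amino-acid gradient retention times, clogP, and the log van der Waals volume
(`config_cs2()`). Nothing in the code depends on these particular
descriptors; any K ≥ 1 named columns work.

The ordinary least-squares fit (`fit_mlr()`, the *control* model) minimizes
absolute squared retention-time error. The package's central idea is that
the quantity many users care about — the **elution order**, i.e. the ranking
of the analytes by retention time — deserves to be an explicit objective.
Both objectives are *relative* root-mean-square errors in percent:

* `f1 = %RMSE(tR) = 100·sqrt(mean(((t̂ − t)/t)²))`,
* `f2 = %RMSE(order)`, the same form applied to elution ranks.

Dividing rank errors by the observed rank makes `f2` weight the front of the
chromatogram heavily: swapping ranks 1 and 2 costs far more than swapping
ranks 40 and 41. That matches chromatographic practice, where early-eluting,
closely spaced peaks are the identification bottleneck, and it explains why
`f2` can exceed 100 % for badly misordered sets.

Ranks are 1-based and ties in retention time are broken by original row
order (a stable sort), so `elution_ranks()` always returns a permutation and
every downstream computation is deterministic.

### The signed "literal" error variant

The error formula is also available as a signed mean relative error with no
squaring or root (`rmse_variant = "literal_eq6"`). It is retained strictly
for auditing: it can be negative, is not a distance, and is never used by
the optimizer by default. `validate_config()` warns whenever it is enabled.

## Multi-objective re-optimization

Minimizing `(f1, f2)` jointly over the coefficient vector is a
two-objective problem whose solution is a Pareto front, not a point.
`optimize_moo()` runs an elitist non-dominated-sorting genetic algorithm —
NSGA-II-style fast non-dominated ranking with crowding-distance diversity,
binary tournament selection, simulated-binary crossover (η_c = 15) and
polynomial mutation (η_m = 20). The GA flavor was an open design choice; we
chose this combination because it is the standard, robust workhorse for
small-dimensional two-objective problems and requires no gradient of the
(rank-valued, piecewise-constant) order objective.

Choices that matter:

* **Seeding.** The first individual *is* the MLR coefficient vector; the
  rest are component-wise Gaussian perturbations with sd
  `init_spread · max(|α_k|, 1e-3)` (default `init_spread = 0.1`). With
  elitist environmental selection this guarantees the returned front is
  never worse than the control in either objective.
* **Search box.** SBX and polynomial mutation need finite gene ranges; we
  bound each coefficient to `α_k ± 10 · init_spread · max(|α_k|, 1e-3)`
  around the MLR start. The re-optimized model is meant to be a *re-weighted
  neighbour* of the control, not an unrelated regression, so a generous box
  centred on the start is the right search region; ±α_k (at the defaults)
  has proven ample in every test.
* **Objectives on the training set only.** During evolution `f1`/`f2` are
  evaluated on the Kennard–Stone training rows; test-set metrics are
  computed afterwards and never optimized, avoiding selection leakage.
* **Degenerate individuals.** A non-finite objective value demotes the
  individual to the worst rank (its objectives are set to 1e18) and the run
  continues; only an entirely infeasible initial population aborts.
* **Defaults.** Population 100, 200 generations, crossover probability 0.9,
  per-gene mutation probability 1/(K+1). One run on the 98-analyte preset
  takes a few seconds; population evaluation is vectorized (one matrix
  product per generation plus one rank per individual).
* **Determinism.** The GA seed is part of `ga_params`; identical seeds give
  identical fronts, and the caller's RNG state is saved and restored.

### Knee point and solution selection

The front is numbered by ascending `f1` (an open labelling question; any
fixed convention works as long as it is stated). The **knee** is the
solution closest, in Euclidean distance, to the ideal point (0, 0) after
min–max normalization of both objectives over the front — the simplest
defensible knee definition; ties break toward lower `f1`.

The published selection procedure is prose ("starting from the knee point,
bound the loss of retention predictive ability"); we operationalize it as a
constrained minimization: among solutions whose `f1` exceeds the control's
by at most `max_tr_loss_percent` percent (default 10, the working value of
the original case study), pick the one with minimum `f2`, ties toward lower
`f1`; if nothing is feasible, fall back to the minimum-`f1` solution.
Because the control is seeded into an elitist GA, a budget of 0 % is always
feasible.

## Validation apparatus

**Kennard–Stone split.** Selection runs in autoscaled descriptor space
(zero mean, unit variance over the full table) so the split is
scale-invariant, while the regression itself uses raw descriptors so the
coefficients stay comparable with literature models. The first two training
points are the maximum-distance pair; each next point maximizes its minimum
distance to the selected set; all distance ties break toward the lowest row
index. The training size is `round(ratio·n)` (implemented as
`floor(x + 0.5)` to avoid banker's-rounding surprises).

**Williams plot.** Leverages are `x'(X'X)⁻¹x` against the training design
(intercept included); training leverages sum to the number of parameters.
Residuals — train and test alike — are standardized by the *training*
residual standard deviation (no leave-one-out studentization; the simplest
reading of "standardized residuals"). An exact fit leaves the residual sd at
rounding-error level, which is treated as zero (all standardized residuals
zero, with a warning) rather than dividing by 1e−15. The critical leverage
defaults to `h* = 3(K−1)/N` with K counted as model
variables *including* the intercept — for 3 descriptors and 43 training
analytes, `h* = 9/43 ≈ 0.2093`; the textbook alternative `3(K+1)/N` with K
predictors is available as `leverage_formula = "conventional_k_plus_1"`.
Flags partition the analytes: `x_outlier` (high leverage only), `y_outlier`
(|standardized residual| > 3 only), `xy_outlier` (both), `inside`. Note that
noise-free data still can produce `x_outlier` flags — leverage depends only
on descriptor geometry.

**SRD / CRNN.** The sum of ranking differences between a model's elution
order and the experimental one uses absolute differences (the Spearman
footrule) by default, normalized by the maximum — `n²/2` for even n,
`(n²−1)/2` for odd n (the reversal attains it) — and reported as percent.
The squared variant is available, but the published CRNN reference
statistics for the 98-analyte case (XX1 = 59.00, median = 66.10,
XX9 = 73.2) are only consistent with the footrule null distribution, whose
theoretical mean is `100·((n²−1)/3)/(n²/2) ≈ 66.7 %`; the squared variant
centres near 50 %. The CRNN null is simulated with uniform random
permutations — exactly equivalent to ranking i.i.d. continuous random
numbers — with the 5th percentile (first icosaile, XX1), median, and 95th
percentile (XX9) reported, plus a histogram curve for plotting. For n ≤ 8 an
exact enumeration over all n! permutations (`exhaustive_crnn()`) serves as
the oracle; because the SRD distribution is discrete, simulated quantiles
are compared against exact inverse-CDF quantiles bracketed at p ± 3 binomial
standard errors rather than by naive interpolated-quantile equality.

## The synthetic-data generator

`generate_linear_dataset()` emulates the statistical structure the method
assumes: descriptors from a correlated multivariate normal, retention
linear in the descriptors plus Gaussian noise, all observed retention times
strictly positive (violating rows are redrawn, up to 1000 batches, rather
than truncated — truncation would distort the linear-Gaussian structure the
recovery tests rely on). The heteroscedastic option makes the noise sd
proportional to the noise-free retention (scaled so the sd at the mean
retention equals `noise_sd`), reflecting the larger deviations real gradient
data show toward the retention extremes; on such data plain MLR misorders
early-eluting analytes and the MOO stage has genuine room to trade.

Preset scales are fixed at values a chromatographer would call realistic
for these case studies:

* `preset_cs1_like()` — n = 62, K = 3, α = (18, 5, 2, 1.5), pairwise
  descriptor correlation 0.3, homoscedastic noise sd 1.5 min: control
  %RMSE(tR) lands near 10 %.
* `preset_cs2_like()` — n = 98, K = 3, α = (25, 6, 2.5, 1.5), correlation
  0.5, heteroscedastic noise scale 4 min: control %RMSE(tR) near 15–20 %,
  inside the 8–25 % range typical of the peptide case study.

What the generator does **not** emulate: chromatographic physics (gradient
shape, dwell volume, column chemistry), inter-column correlation of a
multi-column study, non-linear descriptor–retention relationships, and
isomer effects. Passing tests on synthetic data therefore demonstrate the
*algorithmic* claims (recovery, elitism, metric behaviour, null
distributions), not predictive performance on any real column.

## Problem sizes and numerical tolerances

The test suite runs the GA at its default size (population 100, 200
generations) over 20 seeds on the 98-analyte preset for the
improvement-direction property, and at reduced sizes (population 20–40,
10–40 generations) where only mechanics are under test. CRNN uses 100,000
draws in the acceptance script (quantile Monte-Carlo error ≈ 0.05 points)
and 20,000–50,000 in tests. Coefficient-recovery assertions use 1e−8
relative tolerance (exact algebra up to floating point); oracle-equivalence
assertions (normal equations, hat matrix) likewise 1e−8.

## Known limitations

* Linear QSRR only; strongly non-linear retention mechanisms (highly polar
  phases, isomeric peptides) are outside the model class, and the order
  error that remains after re-optimization on such systems is large.
* The order objective is piecewise constant in the coefficients, so the
  front can contain plateaus; distinct coefficient vectors with identical
  objective pairs are collapsed to the first found.
* The selection rule reproduces the published trade-off *directionally*;
  the original work does not state the exact rule, the Pareto-solution
  numbering, or which of two reported solution labels was final.
* Leverage-based domain flags use the fitted model's descriptor set only;
  other applicability-domain definitions (kNN, bounding box) are not
  implemented.
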