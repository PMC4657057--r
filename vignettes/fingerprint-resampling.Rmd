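---
title: "Fingerprint resampling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fingerprint resampling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A nonparametric bootstrap solves essentially the same optimization problem
$\hat\theta^*_b = \arg\max_\theta \, \ell(\theta; X_b)$ for $B$ resampled
data sets $X_1, \dots, X_B$, all drawn from one original data set $X$. When a
single maximization is slow, the whole bootstrap becomes the bottleneck.
Because the resampled likelihood surfaces are extremely similar, information
from resamples already solved can be reused for those still to come. fpboot
implements that idea in three escalating forms:

1. **Better starting values.** The original optimum $\hat\theta_0$ (the fit
   of $X$ itself) is central among the bootstrap optima — the estimated
   bootstrap bias, $\text{mean}_b(\hat\theta^*_b) - \hat\theta_0$, is zero
   exactly when $\hat\theta_0$ equals the mean of the bootstrap optima — so
   it makes an unbiased default start.
2. **Learned warm starts.** Each resample is summarized by a *fingerprint*:
   the finite-difference partial derivatives of *its* log-likelihood
   evaluated at the *original* optimum, up to order $g \in \{1, 2\}$ (for
   $g = 2$, the gradient plus the unique upper-triangular Hessian entries).
   The map fingerprint $\mapsto$ optimum is learned from solved resamples
   and predicts the optimum of each new resample, which becomes the
   optimizer's starting point.
3. **Bypass.** Once predictions are accurate relative to the Monte-Carlo
   error intrinsic to the bootstrap itself, the optimizer adds nothing:
   predictions are taken directly as estimates for $p$ resamples per fully
   optimized one.

Cost is accounted hardware-independently as the number of objective-function
evaluations: optimizer calls plus finite-difference stencil points. The
interpolator's own algebra is excluded — it does not scale with the
difficulty of one objective evaluation, which is the regime the method
targets.

## Why derivatives make good summaries

By Taylor's theorem, the derivatives of $\ell(\cdot\,; X_b)$ at a common
expansion point carry exactly the local information that determines where
the optimum lies. Two worked identities anchor the implementation and its
tests:

* **Exponential model** (mean parametrization, so the MLE is the sample
  average): the first-derivative fingerprint at $\hat\theta_0$ is affine and
  invertible in the resample mean, giving the exact relation
  $\hat\theta^*_b = \hat\theta_0 + \hat\theta_0^2\,\mathcal{F}_1 / n$. One
  fingerprint dimension suffices; the interpolator learns the relation from
  a handful of couples.
* **No-intercept regression with unit error variance**: the log-likelihood
  is quadratic, so a single Newton step from the expansion point is exact:
  $\hat\beta^*_b = \hat\beta_0 - \mathcal{F}_1 / \mathcal{F}_2$. With only
  the gradient ($g = 1$), different resamples can share a fingerprint yet
  have different optima — the gradient alone does not identify
  $\sum x^2$ — so the $g = 1$ prediction error stalls at a positive floor
  while $g = 2$ resolves it. The test suite asserts both behaviours.

## Objective models

Every model implements one contract (`objective_model`): a log-likelihood to
maximize, box constraints, a naive start, a resampler, and a closed-form
oracle where one exists.

* **Exponential** (`model_exponential()`): $\ell(\theta) = -n\log\theta -
  \sum x_i/\theta$, $\theta > 0$; oracle $\bar x$; i.i.d. row resampling.
  The mean parametrization was chosen (rather than the rate) precisely so
  the optimum is the sample average.
* **Regression** (`model_linreg()`): known error variance 1, no intercept;
  oracle $\sum x_i y_i / \sum x_i^2$; pairs resampled.
* **Linear mixed model** (`model_mixed()`): random intercept and slope,
  $y_{ij} = \beta_0 + \beta_1 x_{ij} + u_{0i} + u_{1i} x_{ij} +
  \varepsilon_{ij}$, $(u_{0i}, u_{1i}) \sim N(0, D)$. Two reparametrizations
  reduce the problem to three dimensions: the residual-scaled covariance
  $\Gamma = D/\sigma^2$ is written $LL^\top$ with $L$ lower triangular
  (positive semidefiniteness for free), and $\beta$, $\sigma^2$ are profiled
  out in closed form (GLS and the ML variance estimator). ML, not REML, so
  $\hat\sigma^2(\Gamma) = \sum_i r_i^\top V_i^{*-1} r_i / N$ with $N$ the
  total observation count. Evaluations use per-cluster sufficient statistics
  with the Woodbury and Sylvester identities, so one evaluation is
  $O(\text{clusters})$ regardless of cluster sizes. The Cholesky entries are
  sign-symmetric ($LL^\top$ is invariant to $L \mapsto -L$); predictions and
  evaluation statistics therefore use the recovered, invariant quantities
  $D = \hat\sigma^2 LL^\top$. Resampling is the case bootstrap: whole
  clusters drawn with replacement, relabeled so a cluster drawn twice is two
  units.
* **GEV with a covariate** (`model_gev()`): location
  $\mu_i = \alpha + \beta t_i$, four parameters $(\xi, \sigma, \alpha,
  \beta)$. The density exists only where $1 + \xi (x_i - \mu_i)/\sigma > 0$;
  violations return $+\infty$ (with a flag) rather than raising, so the
  simplex retreats gracefully. $|\xi| < 10^{-8}$ switches to the Gumbel
  limit formulas; continuity at the switch is tested to $10^{-6}$. The naive
  start takes $(\alpha, \beta)$ from the simple regression of $x$ on $t$,
  the scale from the residual standard deviation via the Gumbel moment
  relation $\mathrm{sd} = \sigma\pi/\sqrt 6$, and $\xi_0 = 0.1$; if the
  support fails at the start, the scale is inflated until it holds. These
  moment-style starts are deliberately simple — they are only starting
  values, and their quality is tested behaviourally (finite likelihood,
  $\xi_0$ in $[-0.5, 0.5]$ on Gumbel data), not against any canonical
  formula.

## Synthetic data

The generators define the study conditions; they are ordinary exported
functions, not test fixtures.

* `simulate_exp_data(n = 100, mean = 2)` — the toy setting used throughout:
  $\theta = 2$, $n = 100$, $B = 200$ resamples.
* `simulate_linreg_data(n = 100, beta = 2)` — fixed design equally spaced on
  $(0, 2]$, unit error variance.
* `simulate_mixed_data()` — 30 clusters with sizes uniform on
  $\{40, \dots, 100\}$ (unbalanced, emulating an experience-sampling design
  where subjects miss measurements), standardized within-cluster predictor
  (as a lagged response would be), defaults $\beta = (1, 0.3)$,
  $\sigma^2 = 1$, $D = \begin{pmatrix} 0.4 & 0.1 \\ 0.1 & 0.2
  \end{pmatrix}$ — moderate random-effect variances of the size seen in
  standardized longitudinal outcomes.
* `simulate_gev_data()` — inverts the GEV distribution function with
  $\mu_i = \alpha + \beta t_i$, $t$ equally spaced; defaults
  ($\xi = 0.1$, $\sigma = 1$, $\alpha = 10$, $\beta = 0.5$) emulate a
  century-scale record of daily maximum windspeeds with a mild positive
  trend, in arbitrary units.

What the generators do **not** emulate: missingness mechanisms, serial
dependence within clusters beyond the lagged-predictor structure, seasonal
or heteroskedastic GEV behaviour, or heavy contamination. Passing tests
demonstrate the machinery on clean, correctly specified likelihoods; they do
not certify performance under misspecification.

## The interpolator

"LS-SVM" here is kernel ridge regression with an RBF kernel and a constant
offset feature: training solves $(K + J + \lambda I)\,a = y$ ($J$ the
all-ones matrix), which is the least-squares SVM regression solution. One
single-output model is fitted per parameter dimension; fingerprint
components are standardized to mean 0, scale 1 first (every component starts
out equally important), which also makes predictions invariant to affine
rescaling of any component. Outputs are not standardized — predictions and
errors then live directly on the parameter scale that the simplex
initialization consumes.

Hyperparameters are selected by *exact* leave-one-out cross-validation: for
a ridge-type linear smoother the LOO residual is $r_i / (1 - H_{ii})$ with
$H = K'(K' + \lambda I)^{-1}$, so the whole grid — penalties
$10^{-6}, \dots, 10^{3}$, widths $\{0.3, 1, 3\}\times$ the median pairwise
distance — costs one eigendecomposition per width. The penalty grid extends
to $10^{-6}$ because on noiseless, near-affine relations (the exponential
toy) larger penalties leave visible smoothing bias; LOO protects against
overfitting where the relation is noisy. The per-dimension prediction error
$\varepsilon_k$ is the root-mean-square LOO residual — a single number on
the parameter scale, which is what the simplex needs.

Three rules keep the learned relation trustworthy:

* **Boundary exclusion.** Optima sitting on a box constraint break the
  smooth fingerprint-optimum relation (many fingerprints, one pinned
  optimum), so such couples are excluded from training in that dimension;
  predictions violating a constraint are clipped to the constraint value.
* **Extrapolation avoidance.** Before any prediction is used, the resamples
  whose fingerprints attain the per-dimension minima and maxima
  (deduplicated, at most $2m$ for fingerprint length $m$) plus
  `n_random_initial = 20` random resamples are solved first, from
  $\hat\theta_0$. Later queries are then interpolations.
* **Refit cadence.** The model is refit when the pool has grown by
  $\max(10,\ 10\%)$ couples since the last fit, and refitting stops once the
  pool exceeds 1000 couples (the last model is reused). Exact duplicate
  couples are collapsed before fitting so predictions cannot depend on how
  often a couple was recorded.

Invalid fingerprints (objective undefined at $\hat\theta_0$ for that
resample, e.g. a GEV support violation) route the resample to a full
optimization from the model's naive start rather than inventing an
alternative summary.

## The optimizer

Nelder-Mead with the standard coefficients (reflection 1, expansion 2,
contraction 0.5, shrink 0.5), minimizing the negated log-likelihood, with
$+\infty$ returned outside the box constraints (no projection — consistent
with the GEV support handling). Convergence requires *both* the maximum
infinity-norm spread of the vertices and the spread of their function values
to drop below their tolerances; both default to $10^{-6}$. A safety cap of
`2000 * dim` evaluations exists but is never reached in practice. Every
objective call is counted, including the initial vertices; an external
counter reproduces the reported totals exactly (tested).

Two simplex initializations:

* **Default:** vertex $k{+}1$ multiplies component $k$ by 1.05, or sets it
  to 0.00025 if zero — the convention of the classic simplex
  implementations in mainstream numerical environments.
* **Prediction-scaled:** vertex $k{+}1$ offsets component $k$ additively by
  $\max(\varepsilon_k, \text{tol}_x)$. When the start is a predicted
  optimum, the simplex should only search a region matching the prediction's
  uncertainty; the additive form is used because $\varepsilon_k$ is an
  absolute error scale, and the $\text{tol}_x$ floor keeps the simplex
  nondegenerate when $\varepsilon_k \approx 0$.

## The driver

`fpr_run(data, model, plan, seed)` executes one full run. The plan names the
variant: `naive`, `original_optimum`, `warm_start` (predictions as starts),
or `bypass` (with ratio $p \ge 0$; $p = 0$ is identical to `warm_start`).
For fingerprint variants all $B$ fingerprints are computed up front — the
extrapolation scan needs them — and their cost is charged up front on the
cost axis. Bypassing interleaves strictly "one optimized, then $p$
predicted", and the total number of estimates never exceeds $B$: with
$p = 3$, 200 optimized estimates license 600 predicted ones (800 total), and
if 1800 estimates already exist of a 2000 budget, only 200 more predictions
are appended. Only optimizer-based couples enter the training pool.

Randomness descends from one root seed through separate child streams for
resampling and initial-phase selection, so different variants at the same
seed process identical resamples, and identical seeds give byte-identical
record files.

## Evaluation

The 2.5% percentile bound is the ascending order statistic with floored rank
$\max(1, \lfloor \alpha B \rfloor)$. The weighted version applies the same
flooring convention in weight units — the largest value whose normalized
cumulative weight does not exceed $\alpha$, floored at the first order
statistic — which reduces exactly to the unweighted rule under equal
weights. (A "smallest value with cumulative weight $\ge \alpha$" rule would
disagree with the floored rank whenever $\alpha B$ is not an integer.)

Accuracy curves score each prefix of the estimates, in processing order,
against a reference percentile pooled from strictly more estimates
(20,000 oracle resamples for the toys; pooled runs otherwise). Because the
initial phase solves potentially extreme resamples first, early prefixes
over-represent the tails; prefix $b$ therefore down-weights record $j$ by
$\min(1, b/\text{index}_j)$ — a weight that is 1 for every record once all
estimates are used, so the correction affects only the trajectory, never the
final estimate.

Speed-ups are read off at two accuracy levels derived from the
original-optimum baseline: *high* is approximately the baseline's lowest
error (implemented as 1.05 times its minimum — all variants share the same
Monte-Carlo error floor, so demanding the exact minimum would ask a variant
to beat the statistic that defines the level), and *medium* doubles the
baseline's lowest error. Curves are noisy at desk scale; the acceptance
script averages curves over 10 independent bootstrap processes on the same
original data before measuring crossings, the same device the original
analysis uses at larger scale.

`parallel_replay(run, data, cores = C)` re-executes the schedule with the
training pool frozen at batch boundaries: estimates in the same batch of $C$
cannot learn from each other. $C = 1$ reproduces the serial run identically;
$C \ge B$ disables learning entirely while fingerprint costs remain, so the
run costs at least as much as the original-optimum variant. One caveat
observed at desk scale: for small $C$ the batching changes *when* refits
happen (they trigger at batch boundaries), which can perturb costs a few
percent in either direction; the systematic cost increase from delayed
learning only dominates once batches span a meaningful fraction of the run.
The replay test therefore probes $C \in \{1, B/3, B\}$.

## Problem sizes

The package's own test and acceptance workloads use the toy conditions
$\theta = 2$, $n = 100$, $B = 200$ (exponential), $\beta = 2$, $n = 100$
(regression), 20-replication medians for stochastic properties, runs of
$B = 60$ for orderings and replays, mixed-model recovery at 70 clusters of
60–80 observations, and GEV recovery at $n = 5000$. These sizes make every
property measurable in seconds while leaving the asymptotic claims to the
identities and oracles tested exactly.

## Known limitations

* Objectives are treated as unimodal; multimodal surfaces would make the
  fingerprint-optimum relation discontinuous across basins.
* The error a bypassed prediction injects into the final confidence bound is
  not propagated formally; the bypass ratio $p$ is the user's dial between
  speed and that unquantified error.
* The interpolator is the LS-SVM path only; the module boundary would admit
  other regressors (e.g. spline-based) but none is shipped.
* REML profiling, richer random-effect structures, and GEV covariates in
  scale or shape are out of scope.
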