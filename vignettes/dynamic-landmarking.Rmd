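---
title: "Spline-smoothed landmarking: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spline-smoothed landmarking: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its statistics: the model and
its assumptions, what each tunable parameter does, what the synthetic
cohort generator emulates (and does not), the numerical choices, and the
design decisions that were genuinely open. It states no empirical result
that the test suite does not itself compute.

## 1. The landmark supermodel

Dynamic prediction asks, at a landmark time $s$ during follow-up: given
that a patient is still at risk at $s$, with current marker values $X(s)$
and fixed covariates $Z$, what is the probability of surviving another $t$
months? The working model per landmark is a Cox model on the residual time
scale,

$$h_s(u \mid X(s), Z) = h_{s,0}(u)\, \exp\{X(s)'\beta(s) + Z'\theta\},
\qquad u \ge s,$$

and the package fits all landmarks jointly as a *supermodel*: one stacked
partial likelihood over every (patient, landmark) at-risk row,

* **stratified by landmark** — each stratum $s$ has its own nonparametric
  baseline hazard, estimated by the Breslow formula
  $\hat H_{s,0}(u) = \sum_{t_j \le u} d_j / \sum_{i \in R_s(t_j)}
  e^{\hat\eta_i}$, with risk sets left-truncated at $s$ (rows enter at $s$
  on the original time scale; the clock is not reset, which keeps the
  at-risk bookkeeping auditable);
* with **shared coefficients across strata**: each time-dependent covariate
  enters through interaction columns $x \cdot \phi_i(s)$, so its log hazard
  ratio $\beta(s) = \sum_{i=1}^k \alpha_i \phi_i(s)$ varies smoothly over
  landmark time, while fixed covariates keep one coefficient $\theta$;
* with **cluster-robust (sandwich) variance** by patient, since a patient
  contributes one row per landmark at which they are at risk and those rows
  are strongly dependent. Score residuals are aggregated within patient
  before the outer product; the model-based covariance is retained
  alongside.

A static Cox model is recovered exactly as the special case of a single
landmark and a constant-only basis — the test suite asserts agreement with
an independent Newton–Raphson partial-likelihood implementation to 1e-6 in
the coefficients and 1e-8 in the Breslow increments.

The maximization itself is delegated to `survival::coxph` on the
counting-process representation `(start = s, stop = T̃, event)` with
`strata()` and `cluster()`; everything the supermodel adds — the basis
design construction, per-stratum baselines referenced to covariate value
zero, coefficient trajectories, the time-varying Wald test, prediction and
calibration — is implemented in this package.

## 2. The basis

The default basis is a constant function plus $m = 4$ Wendland C2 kernels
$\psi(r) = (1-r)^4(4r+1)$ centered at equally spaced nodes over the
landmark range, with support radius twice the node spacing (so on a 0–12
month grid: nodes 0, 4, 8, 12, radius 8, $k = 5$). Choices and their
reasons:

* **Wendland C2**: compactly supported (distant landmarks do not influence
  each other's coefficient), positive definite, and twice continuously
  differentiable — the minimal-smoothness member of the family; the order
  beyond C2 is not identifiable from any statement of the method, so the
  family is a pluggable `basis_spec()` rather than a constant.
* **Constant component included by default**: a time-constant effect then
  lies exactly in the span, and the Wald test of "is the effect constant?"
  becomes the null hypothesis that the $k-1$ kernel coefficients vanish
  (statistic $\hat\alpha_{nc}' \hat V^{-1} \hat\alpha_{nc} \sim
  \chi^2_{k-1}$ with the cluster-robust $\hat V$).
* **Approximation error**: the default span does not contain non-constant
  polynomials exactly; projecting a linear trend of slope 0.03/month over
  0–12 months onto the span leaves a residual of at most ~0.013 in the log
  hazard ratio, an order of magnitude below the sampling error at the
  sample sizes the recovery tests use. Users fitting steeper trends over
  longer ranges should add nodes.
* A `transform` slot allows any invertible linear reparameterization of the
  basis; fitted trajectories, likelihood and predictions are invariant
  (asserted to 1e-6 in the suite), which is the practical check that
  results depend on the span, not the parameterization.

## 3. Landmarking the data

`build_landmark_dataset()` stacks, for each landmark $s$ in the grid
(default integer months 0–12) and each patient with $\tilde T > s$, the
most recent measurement of each time-dependent variable taken at or before
$s$ (last observation carried forward). When several measurements fall in
the month ending at $s$, the latest is used — a consequence of taking the
most recent value overall. Two behaviours are deliberately exposed because
the underlying convention is ambiguous in the field:

* **Carry-forward horizon**: by default a value is carried indefinitely
  (`max_staleness = Inf`), since excluding patients between sparse visits
  would change the at-risk population; setting `max_staleness` drops
  patients whose freshest value at $s$ is older than the cutoff. Neither
  behaviour is asserted as "the" convention; per-variable `staleness_*`
  columns make the choice auditable.
* Patients with *no* measurement of a requested variable by $s$ are omitted
  from that landmark (they cannot be scored), mirroring the usual
  exclusion of patients with no marker data at all.

Row counts are property-tested against a brute-force double loop, and the
no-leakage invariant (no row uses a measurement after its landmark) plus
risk-set nestedness are asserted directly.

## 4. Evaluation: IPCW time-dependent AUC

At a (landmark, horizon) pair, cases are patients observed to die in
$(s, s+t]$, controls are patients under observation beyond $s+t$; censored
patients with $\tilde T \le s+t$ belong to neither class, and the two
classes are reweighted by the inverse of the estimated censoring survival
(cases at their own $\tilde T$, controls at $s+t$) to undo that selection.
A case–control pair scores 1 if the case's predicted survival is strictly
lower, ½ on ties. Numerical and design notes:

* The printed pair-sum definition is internally inconsistent about whether
  cases are defined by $\tilde T \le t$ or $\tilde T \le s+t$; the
  landmark-anchored $s+t$ scale is used throughout, matching the
  sensitivity/specificity definitions.
* The censoring survival is conditioned on being uncensored at the landmark
  by renormalization $\hat S_C(\cdot)/\hat S_C(s)$ — the standard IPCW
  choice when the conditioning is left implicit.
* The censoring model is a Cox model with censoring as the event (age and
  gender by default, configurable, covariate-free allowed, in which case it
  reduces to $\exp(-\hat H)$ with the Nelson–Aalen cumulative hazard — the
  first-order equivalent of the Kaplan–Meier product limit). It is fitted
  once on training patients; refitting per landmark is possible by calling
  it on the at-risk subset, but is not the default.
* The implementation is a sorted weighted rank computation, $O(n \log n)$;
  the acceptance suite proves it equal to the brute-force double loop to
  1e-12 on 100 random instances with and without censoring, and equal to
  the classical Mann–Whitney AUC when no weighting is applied.
* Optional weight capping at a quantile (`weight_cap_quantile`) is exposed
  but off by default: near-zero censoring survival inflates weights, but
  truncation changes the estimand, so it is opt-in.

**Bootstrap.** Patient-wise resampling with replacement of the validation
at-risk set, 100 iterations by default, percentile 95% intervals.
Predictions and the censoring model are held fixed (they are training-set
quantities); only the evaluation set varies. For two models evaluated on
the same resamples, the two-sided p-value is twice the smaller tail
fraction of bootstrap differences, floored at $1/n_{boot}$. Resamples with
no cases (or no controls) are skipped with a warning; more than half
skipped is an error — except inside `evaluate_grid()`, where a degenerate
cell reports its point estimate with a missing CI and a note instead of
aborting the table.

**Aligned comparisons.** A static baseline model evaluated at landmark $s$
and horizon $t$ is scored on the *same* at-risk patients as the dynamic
models, using its baseline covariate values and the shifted horizon
$s + t$ from its own landmark — otherwise the comparison would confound
model form with evaluation population. Any single-landmark fit is treated
this way by `evaluate_grid()`.

## 5. Calibration

For patient $i$ at risk at $s$, the model-expected number of events over
their own follow-up is $e_{i,s} = \hat H_{s,0}(\tilde T_i)
\exp\{X_i(s)'\hat\beta(s) + Z_i'\hat\theta\}$, and $m_{i,s} = \delta_i -
e_{i,s}$ is the martingale residual; on training data these sum to zero
within every landmark stratum (the Breslow score identity, asserted to
1e-8). Using the full follow-up in the offset — rather than capping at a
horizon — lets the offset absorb unequal exposure; the fixed 1-month
horizon enters only through the *grouping* of patients into deciles of
predicted survival.

The calibration endpoint is a Poisson regression of $\delta_i$ on the $q$
group indicators with offset $\log e_{i,s}$, no intercept, offset
coefficient fixed at 1. Its MLE is available in closed form,
$\hat\gamma_g = \log(O_g/E_g)$ with information $O_g$, which the package
uses as the primary solver (the iterative `glm` route is retained and the
identity asserted to 1e-10). Although $\delta_i$ is binary, the martingale
variance of $\delta_i - e_{i,s}$ is $E(e_{i,s})$ — not the Bernoulli
variance — so the Poisson information is the right scaling. Both per-group
Wald intervals and the global test ($\sum_g O_g \hat\gamma_g^2 \sim
\chi^2_{df}$) are reported, since group-level and global statements answer
different questions. Groups with zero observed events have
$\hat\gamma_g = -\infty$; they are reported with an exact one-sided Poisson
upper limit and excluded from the global statistic with a df reduction and
a warning. With fewer distinct predictions than groups, groups collapse
with a warning; exact ties are otherwise broken by stable input order.

## 6. The synthetic cohort: a stated world

`cohort_config()` defaults emulate the structure of an advanced-NSCLC
real-world cohort followed from first-line treatment start — *structure*,
not the proprietary data themselves:

* fixed covariates age ~ N(68.2, 9.6²) years, gender ~ Bernoulli(0.463);
* an albumin-like continuous marker starting at N(3.7, 0.5²) g/dL,
  drifting −0.02 g/dL/month with 0.15 visit-level noise; an ECOG-like
  ordinal marker 0–4, a rounded, clipped latent random walk drifting
  upward 0.05/month;
* clinic visits at time 0 and then exponential gaps with mean 1 month
  (irregular and non-aligned across patients — the measurement pattern the
  method exists to handle); the visit-frequency of the emulated cohort is
  not published, so this mean is a stated assumption;
* dynamic log hazard ratios interpolating the published effect
  trajectories linearly over 0–12 months: per +1 g/dL albumin, HR 0.58 at
  baseline strengthening to 0.43 at 12 months; per +1 ECOG step, HR 1.38
  strengthening to 1.70;
* baseline hazard 0.206/month, calibrated once so the simulated marginal
  median OS is ≈ 11.6 months (the published cohort median); censoring
  Exp(0.02)/month plus a 36-month administrative cutoff (assumption).

Event times are drawn *exactly*: the hazard is constant between
change-points (visit times; plus a fine grid, default 0.25 months, when
$\beta(t)$ is non-constant, the one discretization approximation in the
general mode), and inverse-transform sampling inverts the piecewise-linear
cumulative hazard. Latent truth (true event and censoring times) is kept
alongside the observable data.

**What a green test does and does not establish.** The generator's visit
process is non-informative (independent of health status), markers follow
simple Gaussian mechanisms, and censoring is independent. Real cohorts
violate all three (sicker patients are measured more often, labs are
skewed, censoring may be informative). A passing suite establishes that the
estimators do what they claim *under the assumed world*, not that the model
is well-specified for any particular dataset.

**The landmark-faithful mode and the `window` option.** With
`landmark_faithful = TRUE`, visits fall on integer months, markers are
constant within each month, and $\beta(t)$ is evaluated at the floor month,
so the hazard is exactly constant on month intervals. This matters because,
with full residual follow-up, the landmark supermodel fitted to data with a
drifting $\beta(t)$ has *no exact estimand*: the partial-likelihood limit
at stratum $s$ is a follow-up-weighted average of $\beta(u)$ over $u > s$.
That is a property of landmarking itself, not of this implementation. To
give parameter-recovery tests an unambiguous truth, `fit_dpm(window = w)`
optionally caps each stratum's follow-up at $s + w$ (classic sliding-window
landmarking). On faithful data with $w = 1$ month, both $x(u)$ and
$\beta(u)$ are constant over the stratum's window, the model is exactly
correctly specified, and the estimand is $\beta(s)$ — the configuration the
recovery and power tests use. The default remains `window = Inf`, because
the production use case predicts several horizons from one fit.

## 7. Numerical choices, degenerate inputs, limitations

* **Ties**: Breslow everywhere (consistent with the Breslow baseline);
  Efron is offered for the coefficients, but baselines always use the
  Breslow form.
* **Baselines** are referenced to covariate value zero (uncentered linear
  predictors), so $e_{i,s}$ and predictions compose without hidden
  centering constants; $H_{s,0}(s) = 0$ by construction and horizon-0
  predictions are exactly 1.
* Strata with zero events contribute no events (warning); all strata empty
  is an error. Non-convergence and singular Wald blocks raise dedicated
  numerical errors (the latter suggesting fewer basis functions).
* Prediction at an off-grid landmark uses the nearest stratum's baseline
  with a warning; coefficient evaluation outside the fitted range is
  flagged as extrapolation but computed (compact support makes far
  extrapolations collapse to the constant component).
* CIs are normal-quantile 95% throughout; the bootstrap CI is percentile.
* Serialization is JSON (`write_dpm`/`read_dpm`), round-trip stable to
  1e-12 in coefficients, covariance and predictions. Pipeline configs are
  JSON (YAML support was dropped: no YAML parser in the supported
  dependency set).
* **Limitations**: no joint modelling of the marker process (deliberately —
  landmarking trades full-likelihood efficiency for robustness to marker
  model misspecification); no penalized basis fitting, so the node count is
  a bias–variance choice the user owns; informative visit schedules are
  neither generated nor corrected for; recalibration to new populations is
  out of scope.
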