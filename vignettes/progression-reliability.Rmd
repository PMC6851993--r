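---
title: "Separating disease progression from measurement error in longitudinal rating scales"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating disease progression from measurement error in longitudinal rating scales}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(progrel)
```

## The problem

Clinical rating scales such as the MDS-UPDRS are the workhorse outcome of
longitudinal Parkinson's disease studies, yet an individual assessment is a
noisy snapshot: inter- and intra-rater variability, mood, time of day, and —
for the motor exam — the short-term symptomatic effect of dopaminergic
medication all perturb the score without saying anything about the disease's
long-term course. When one looks at two *consecutive* 1-year change scores
in such a cohort, they are negatively correlated: a patient whose score
jumped up one year tends to come back down the next. That is regression
toward the mean, and it signals that observed change scores mix true
progression with a substantial error component.

`progrel` quantifies that mixture. It models each patient's latent severity
as a random walk with a population drift, observed with Gaussian error, and
reports the **within-subject reliability of 1-year change scores**: the
fraction of change-score variance that reflects true long-lasting change.

## The model

For patient $i$ at month $t$ (months since the screening visit):

$$y_{t,i} = \theta_{t,i} + v_{t,i}, \qquad v_{t,i} \sim N(0, \sigma^2_E)$$
$$\theta_{t,i} = \theta_{t-1,i} + w_{t,i}, \qquad w_{t,i} \sim N(\mathrm{trend}, \sigma^2_{\Delta T})$$

with initial state $\theta_{0,i} \sim N(m_0, C_0)$. The five estimable
parameters are:

| parameter | meaning | units |
|---|---|---|
| $\sigma^2_E$ | measurement error + short-term fluctuation variance | score$^2$ |
| $\sigma^2_{\Delta T}$ | variance of true change per unit time | score$^2$/unit |
| trend | mean population progression per unit time | score/unit |
| $m_0$, $C_0$ | initial latent severity mean and variance | score, score$^2$ |

One shared parameter set describes the whole population, so the *average*
progression is linear in time, while individual trajectories wander around
it through $w_{t,i}$. The model is fitted on a monthly grid; months between
scheduled visits are missing values, which the Kalman filter handles
exactly (the state prediction propagates with no update). Because both the
trend and $\sigma^2_{\Delta T}$ accumulate linearly in time, estimates are
reported per year of follow-up by multiplying the monthly values by 12
(`annualize()`).

A 1-year change score is the difference of two noisy measurements, so its
variance is $\sigma^2_{\Delta X} = \sigma^2_{\Delta T} + 2\sigma^2_E$ (annual
units), and the within-subject reliability is

$$\hat r_{\Delta\Delta} = \frac{\hat\sigma^2_{\Delta T}}
 {\hat\sigma^2_{\Delta T} + 2 \hat\sigma^2_E}.$$

The same algebra links reliability to the lag-1 correlation $\rho$ of
consecutive equal-interval change scores: under the model
$\rho = -\sigma^2_E / \sigma^2_{\Delta X}$, hence
$r = 1 + 2\rho$ — the mechanism behind the observed negative correlation.
`change_score_correlation()` estimates $\rho$ directly from data and the
test suite verifies the identity on large simulations.

## Two design choices in the likelihood

Two details of the state-space contract were genuinely open and are fixed
here as follows:

* **Month 0 receives no transition step.** The first scheduled observation
  is distributed $N(m_0, C_0 + \sigma^2_E)$ directly; the random-walk
  innovation applies only *between* months. The alternative (one $w$-step
  before the first observation) merely re-parameterizes $m_0, C_0$ and is
  not distinguishable from data.
* **The trend enters the prediction step directly.** Some state-space
  toolkits require embedding a drift by augmenting the state with a
  constant; mathematically the two formulations are identical, and the
  direct form keeps the state scalar and the contract simple.

Series are used up to each patient's last observation; trailing months
contribute nothing to the likelihood either way.

## Estimation

`fit_mle()` maximizes the pooled log-likelihood
$\sum_i \ell_i(\sigma^2_E, \sigma^2_{\Delta T}, \mathrm{trend}, m_0, C_0)$
with variances on the log scale (so the optimizer is unconstrained), using
BFGS from moment-based starting values:

* $\sigma^2_E$ start: half the variance of first differences at adjacent
  annual visits (the other half goes to the annual $\sigma^2_{\Delta T}$
  start) — the change-score variance decomposition used as its own
  initializer;
* trend start: mean observed change per month;
* $m_0$, $C_0$ start: mean and variance of each patient's earliest score.

Three additional deterministic restarts rescale the two variance starts by
4, 1/4 and 16 to guard against local optima; the best final likelihood
wins. Convergence is declared by the optimizer at a relative tolerance of
`1e-10` on the objective (well below 1e-8 in log-likelihood units at these
sample sizes); non-convergence is flagged in the result, never thrown. A
variance estimate below `1e-6` is reported as exactly 0 with a boundary
flag. $m_0$ and $C_0$ are free parameters of the likelihood, not moment
plug-ins. The two part III medication conditions (OFF, ON) are always
fitted as separate independent models.

## Inference

`bootstrap_ci()` implements the simple percentile bootstrap with the
*patient* as resampling unit: each replicate draws patients with
replacement, refits all five parameters (warm-started at the full-sample
estimate), and the CI is the empirical $\alpha/2$ and $1-\alpha/2$
percentiles across replicates, with linear interpolation between order
statistics (`quantile()` type 7 — the convention had to be fixed
somewhere and this is R's default). No BCa or studentization: percentile
intervals are the method's specified inferential summary. Defaults are
`n_boot = 1000`, `alpha = 0.05`.

`compare_washout()` assesses whether a longer medication washout before an
OFF motor exam lowers the error variance. To maximize power it resamples
patients *first* and applies both washout thresholds to the same replicate,
refitting both models and collecting paired differences; the reported
one-sided p is the fraction of replicates with difference $\ge 0$ (double
it for a two-sided statement). Threshold comparisons are strict
(`> 6` hours, `> 14` hours); untreated patients are OFF by definition.

## Factor subscores

`extract_factors()` implements principal-component factoring of the pooled
item correlation matrix (Pearson; rows with any missing item dropped)
followed by raw varimax rotation, with columns sign- and order-normalized.
The number of factors is a configuration input chosen from the scree
elbow (`scree_eigenvalues()`) — deliberately not automated, since elbow
selection is a judgment call. Factor subscores are loading-weighted sums of
*raw* item scores (`score_factors()`), so with unit loadings they reduce to
the plain subtotal; the downstream state-space model is indifferent to this
affine choice of scale. Pooling all longitudinal visits as rows ignores the
within-patient dependence between rows; this affects only the factoring
step, which is used descriptively, not inferentially.

## What the synthetic generator emulates — and what it does not

`simulate_cohort()` reproduces the *structure* of a de novo PD cohort like
PPMI: 423 patients; screening at month 0 and baseline at month 1; 3-month
visits in year 1 and 6-month visits to month 61 for parts I/II; the motor
exam OFF condition only at screening and annual visits, with hours since
last dose log-normal (median 14 h) once therapy has started; ON exams about
1 h postdose at annual visits for treated patients; therapy starting
uniformly between months 2 and 24 (no one treated at inclusion); monotone
loss to follow-up with per-visit hazard 0.0125, retaining roughly 85% of
patients at month 61. Ground-truth parameters default to the reference
estimates of `ppmi_reference_params()`, with baseline means/SDs as
$m_0$/$\sqrt{C_0}$.

Deliberate simplifications, which bound what passing tests can claim about
real data:

* Scores are generated *from the model*: Gaussian, continuous, unclipped —
  real subtotals are non-negative integers and real residuals have heavier
  tails (the diagnostics are designed to detect exactly this, see below).
* The part III ON condition is generated from its **own independent latent
  path** with the ON reference parameters and a baseline mean lowered by a
  symptomatic-benefit offset (6 points). Tying ON to the OFF latent path
  would force both conditions to share one true-change variance, which
  contradicts the reference estimates; the package therefore treats the
  coupling between conditions as out of scope, exactly as the fitting side
  does.
* Attrition is a single geometric hazard, not the mixture of reasons real
  cohorts have; only the overall retention level is emulated.
* No covariates (age, sex, cognition) — the model deliberately measures the
  *magnitude* of progression variance, not what explains it.

`simulate_items()` plants a known simple-structure loading matrix
(default: 11 items in blocks of 4/4/3 with loadings 0.8), discretizes to
the 0-4 item range, and returns the truth for recovery tests. Discretizing
costs a little attenuation, which is why recovery is asserted to 0.1, not
machine precision. `inject_dose_effect()` plants extra observation noise
on short-washout OFF assessments to give `compare_washout()` a known
truth.

## Diagnostics

`residual_report()` computes both residual families: standardized one-step
innovations (iid $N(0,1)$ under the model) and smoothed residuals
($y_t$ minus the estimated true state). It returns normal QQ pairs, a
Shapiro-Wilk p-value (diagnostic only — no data are rejected, matching the
analysis the model is built for), the lag-1 change-score correlation and
per-visit group summaries (`group_trajectories()`: median with 10% and 25%
bands around it, missing values excluded). Heavy-tailed contamination
shows up as QQ tails above the diagonal and a small Shapiro-Wilk p; the
test suite plants $t_3$ noise to confirm the flag fires.

## Problem sizes used by the test suite

The tests exercise the full study scale where the claim depends on it
(n = 423 with the complete visit schedule for parameter recovery; n =
10,000 for the change-score law), and reduced designs where the claim is
structural: bootstrap coverage uses 50 truths of 60 patients on the annual
schedule at 200 replicates, and the washout null calibration 15 cohorts of
200 patients at 100 replicates. These sizes are the package's own choice
of a Monte Carlo design with comfortable margins around each assertion.

## Limitations

* Gaussian observation noise understates tail behavior seen in real part
  I/II scores; the fitted variances remain interpretable as second moments,
  but outlier-driven inflation of $\hat\sigma^2_E$ is possible.
* $\sigma^2_E$ and $\sigma^2_{\Delta T}$ are assumed constant over the
  5-year window — defensible in an early, homogeneous cohort, not beyond
  it.
* $\sigma^2_{\Delta T}$ measures long-lasting change of any origin,
  including sustained treatment effects, not neurodegeneration alone.
* The washout comparison is observational: time since last dose is not
  randomized, so confounding by disease severity cannot be excluded by the
  machinery here.
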