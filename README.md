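# progrel

Separating true disease progression from measurement error in repeated
clinical rating-scale scores.

Longitudinal studies of Parkinson's disease lean on the MDS-UPDRS to
measure how patients change, but an individual assessment is a noisy
snapshot of the underlying disease state. Consecutive 1-year change scores
are *negatively* correlated in real cohorts — regression toward the mean —
which means observed changes are partly error. `progrel` is for
biostatisticians and clinical researchers who need to know *how much*:
it decomposes change-score variance into a true-progression component and
an error component, and reports the **within-subject reliability of
1-year change scores**.

## The model and the statistic

Each patient's latent severity θ follows a random walk with a population
drift, observed with Gaussian error, on a monthly grid (missing months are
handled exactly by the Kalman filter):

    y[t,i] = θ[t,i] + v[t,i],        v ~ N(0, σ²_E)
    θ[t,i] = θ[t−1,i] + w[t,i],      w ~ N(trend, σ²_ΔT)
    θ[0,i] ~ N(m0, C0)

All five parameters (σ²_E, σ²_ΔT, trend, m0, C0) are estimated jointly for
the study population by pooled maximum likelihood. Because a 1-year change
score is the difference of two noisy measurements, its variance is
σ²_ΔT + 2σ²_E (annual units), and the within-subject reliability is

    r̂_ΔΔ = σ̂²_ΔT / (σ̂²_ΔT + 2 σ̂²_E)

Confidence intervals come from a simple percentile bootstrap that
resamples whole patients. The package also provides principal-component
factor subscores with varimax rotation, a paired-bootstrap comparison of
medication-washout thresholds for OFF motor exams, residual diagnostics,
and a synthetic cohort generator that emulates the PPMI visit structure
with known ground truth.

## Worked example

Simulate a 423-patient cohort at the reference part II parameters, fit the
model, and bootstrap the reported quantities:

```r
library(progrel)

sim <- simulate_cohort(generator_config(n_patients = 423, seed = 11,
                                        scales = "part2"))
fit <- fit_mle(sim$cohort, "part2")
fit
#> Latent progression model fit [part2]
#>   423 patients, 5509 observations; log-likelihood -13960.92
#>   sigma_e2 = 3.686   sigma_dt2 = 7.873 /yr   trend = 1.031 /yr
#>   m0 = 5.62   c0 = 14.13
#>   within-subject reliability of 1-year changes: 0.516

bootstrap_ci(sim$cohort, "part2", n_boot = 200, seed = 12)
#> Within-subject reliability analysis [part2], 200 bootstrap replicates
#>          sigma_e2 sigma_dt2_annual trend_annual  r_dd
#> estimate    3.686            7.873        1.031 0.516
#> 2.5%        3.405            6.951        0.896 0.473
#> 97.5%       3.937            8.701        1.154 0.558
```

The cohort was generated with σ²_E = 3.66, σ²_ΔT = 7.22/yr and trend
1.03/yr, so the fit recovers the truth within sampling error: about half
the variance of an observed 1-year change in part II scores reflects real
long-term change (r̂ ≈ 0.5), the rest is noise. `residuals(fit)`,
`predict(fit)` (smoothed latent paths), `plot(fit)` and
`change_score_correlation()` provide the model-adequacy side;
`compare_washout()` tests whether a longer pre-assessment washout lowers
σ²_E.

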