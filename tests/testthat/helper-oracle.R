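# Independent brute-force oracle for the state-space likelihood: under the
# local level model with drift, the observations at months t1..tk are
# jointly Gaussian with mean m0 + trend * t and covariance
#   c0 + sigma_dt2 * min(s, t) + sigma_e2 * 1[s == t],
# so the marginal log-likelihood is a multivariate-normal log-density.
mvn_loglik_oracle <- function(y, months, params) {
  obs <- which(!is.na(y))
  if (length(obs) == 0) return(0)
  t <- months[obs]
  mu <- params$m0 + params$trend * t
  S <- params$c0 + params$sigma_dt2 * outer(t, t, pmin) +
    diag(params$sigma_e2, length(t))
  ch <- chol(S)
  z <- backsolve(ch, y[obs] - mu, transpose = TRUE)
  -0.5 * (length(t) * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2))
}

# Raw varimax criterion (summed within-column variance of squared loadings).
varimax_criterion <- function(L) {
  p <- nrow(L)
  sum(colSums(L^4) - colSums(L^2)^2 / p)
}

# Small long-format cohort fixture: `n` patients observed at `months` on
# one scale, values filled deterministically.
make_fixture_cohort <- function(n = 2, months = c(0, 13),
                                scale_id = "part2",
                                values = NULL, schedule = NULL) {
  if (is.null(schedule)) schedule <- months
  grid <- expand.grid(month = months, patient_id = sprintf("P%02d", seq_len(n)))
  if (is.null(values)) values <- seq_len(nrow(grid)) + 4
  cohort_table(data.frame(patient_id = grid$patient_id, month = grid$month,
                          scale_id = scale_id, subtotal = values,
                          hours_postdose = NA_real_, on_therapy = FALSE),
               schedule = schedule)
}

# Random monthly-grid parameters for property-style loops.
random_params <- function() {
  model_params(sigma_e2 = runif(1, 0.1, 5), sigma_dt2 = runif(1, 0, 2),
               trend = runif(1, -1, 1), m0 = runif(1, -5, 5),
               c0 = runif(1, 0, 4))
}
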