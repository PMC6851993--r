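test_that("pooled MLE is translation-equivariant and handles boundaries", {
  sim <- simulate_cohort(generator_config(n_patients = 80, seed = 11,
                                          scales = "part2"))
  fit <- fit_mle(sim$cohort, "part2")
  expect_true(fit$converged)

  shifted <- sim$cohort
  shifted$subtotal <- shifted$subtotal + 100
  fit2 <- fit_mle(shifted, "part2")
  c1 <- coef(fit); c2 <- coef(fit2)
  expect_equal(c2[c("sigma_e2", "sigma_dt2", "trend")],
               c1[c("sigma_e2", "sigma_dt2", "trend")], tolerance = 1e-3)
  expect_equal(c2[["m0"]], c1[["m0"]] + 100, tolerance = 1e-3)

  # degenerate truth sigma_dt2 = 0: estimate is allowed at the boundary
  pz <- model_params(4, 0, 1, 5, 16, time_unit = "year")
  simz <- simulate_cohort(generator_config(n_patients = 150, seed = 12,
                                           scales = "part2",
                                           params = list(part2 = pz)))
  fz <- fit_mle(simz$cohort, "part2")
  expect_lt(coef(fz, "year")[["sigma_dt2"]], 0.6)

  expect_error(fit_mle(make_fixture_cohort(n = 1, months = c(0, 13)),
                       "part2"), "at least 2 patients")
})

test_that("likelihood at the true parameters beats perturbed parameters", {
  truth <- model_params(3.66, 7.22, 1.03, 5.7, 17.64, time_unit = "year")
  sim <- simulate_cohort(generator_config(n_patients = 423, seed = 13,
                                          scales = "part2"))
  dat <- to_monthly_series(sim$cohort, "part2")
  pm <- deannualize(truth)
  ll_true <- sum(vapply(dat, kalman_loglik, 0, params = pm))
  for (fac in c(0.6, 1.5)) {
    pert <- model_params(pm$sigma_e2 * fac, pm$sigma_dt2 / fac,
                         pm$trend, pm$m0, pm$c0)
    expect_gt(ll_true, sum(vapply(dat, kalman_loglik, 0, params = pert)))
  }
})

test_that("fit methods expose coefficients, residuals and predictions", {
  sim <- simulate_cohort(generator_config(n_patients = 50, seed = 14,
                                          scales = "part2"))
  fit <- fit_mle(sim$cohort, "part2")

  expect_named(coef(fit), c("sigma_e2", "sigma_dt2", "trend", "m0", "c0"))
  expect_equal(coef(fit, "year")[["sigma_dt2"]],
               12 * coef(fit)[["sigma_dt2"]])
  expect_equal(attr(logLik(fit), "df"), 5L)
  expect_output(print(fit), "reliability")
  expect_output(print(summary(fit)), "time unit")

  r <- residuals(fit, type = "innovation")
  expect_equal(nrow(r), fit$n_observations)
  expect_lt(abs(mean(r$residual)), 0.2)   # centered under the model
  rs <- residuals(fit, type = "smoothed")
  expect_equal(stats::sd(rs$residual), 1, tolerance = 1e-9)

  paths <- predict(fit)
  expect_length(paths, fit$n_patients)
  expect_true(all(paths[[1]]$state_var >= 0))

  y1 <- simulate(fit, nsim = 2, seed = 5)
  y2 <- simulate(fit, nsim = 2, seed = 5)
  expect_identical(y1, y2)
  expect_identical(is.na(y1[[1]]), is.na(fit$data$Y))
})

test_that("parameter recovery is unbiased at reduced scale", {
  truth <- ppmi_reference_params()
  truth <- truth[truth$scale_id == "part2", ]
  ests <- t(vapply(1:6, function(s) {
    sim <- simulate_cohort(generator_config(n_patients = 200, seed = 20 + s,
                                            scales = "part2"))
    coef(fit_mle(sim$cohort, "part2"), "year")
  }, numeric(5)))
  m <- colMeans(ests)
  expect_equal(m[["sigma_e2"]], truth$sigma_e2, tolerance = 0.1)
  expect_equal(m[["sigma_dt2"]], truth$sigma_dt2, tolerance = 0.1)
  expect_lt(abs(m[["trend"]] - truth$trend), 0.08)
  expect_lt(abs(m[["m0"]] - truth$m0), 0.5)
})
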