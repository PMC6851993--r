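test_that("generator is a deterministic function of (config, seed)", {
  cfg <- generator_config(n_patients = 30, seed = 41)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(as.data.frame(s1$cohort), as.data.frame(s2$cohort))
  expect_identical(s1$truth$paths, s2$truth$paths)
  s3 <- simulate_cohort(generator_config(n_patients = 30, seed = 42))
  expect_false(identical(s1$cohort$subtotal, s3$cohort$subtotal))
  expect_error(generator_config(n_patients = 5), "seed")
})

test_that("noise-free configuration yields a deterministic line", {
  line <- model_params(0, 0, 12, 0, 0, time_unit = "year")
  sim <- simulate_cohort(generator_config(
    n_patients = 5, seed = 43, scales = "part2",
    params = list(part2 = line), dropout_hazard = 0))
  expect_equal(sim$cohort$subtotal, sim$cohort$month)
})

test_that("attrition is monotone and emulates gradual loss to follow-up", {
  sim <- simulate_cohort(generator_config(n_patients = 400, seed = 44,
                                          scales = "part2"))
  coh <- sim$cohort
  by_pat <- split(coh$month, coh$patient_id)
  sched <- default_schedule()
  for (m in by_pat) {
    att <- sort(unique(m))
    expect_identical(att, sched[seq_along(att)])  # no gaps: dropout is final
  }
  n_by_visit <- table(factor(coh$month, levels = sched))
  expect_true(all(diff(as.integer(n_by_visit)) <= 0))
  # roughly 85% retained at the last visit
  retention <- n_by_visit[["61"]] / n_by_visit[["0"]]
  expect_gt(retention, 0.75)
  expect_lt(retention, 0.95)
})

test_that("therapy timing drives OFF/ON availability and washout hours", {
  sim <- simulate_cohort(generator_config(n_patients = 200, seed = 45))
  coh <- sim$cohort
  off <- coh[coh$scale_id == "part3_off", ]
  on <- coh[coh$scale_id == "part3_on", ]
  expect_true(all(off$month %in% annual_schedule()))
  expect_true(all(on$month %in% setdiff(annual_schedule(), 0)))
  # untreated OFF rows carry no dose timing; treated rows do
  expect_true(all(is.na(off$hours_postdose[!off$on_therapy])))
  expect_true(all(off$hours_postdose[off$on_therapy] > 0))
  # ON assessments happen about 1 hour postdose
  expect_true(all(on$hours_postdose < 6))
  # median washout of treated OFF assessments is around 14 hours
  expect_equal(median(off$hours_postdose[off$on_therapy]), 14,
               tolerance = 0.15)
  # ON only after therapy start
  start <- sim$truth$dt_start[on$patient_id]
  expect_true(all(on$month >= start))
})

test_that("item generator respects the 0-4 range and its planted model", {
  si <- simulate_items(1000, seed = 46)
  expect_true(all(si$items >= 0 & si$items <= 4))
  expect_true(all(si$items == round(si$items)))
  si2 <- simulate_items(1000, seed = 46)
  expect_identical(si$items, si2$items)

  # zero noise, one factor, equal loadings: items perfectly rank-correlated
  L <- matrix(0.9, 4, 1)
  sz <- simulate_items(500, loadings = L, unique_sd = 1e-9, seed = 47)
  co <- suppressWarnings(stats::cor(sz$items, method = "spearman"))
  expect_true(all(co > 0.99))

  expect_error(simulate_items(10, loadings = matrix(1, 2, 3), seed = 1),
               "wider")
})

test_that("planted dose effects change only the targeted records", {
  sim <- simulate_cohort(generator_config(n_patients = 150, seed = 48,
                                          scales = "part3_off"))
  expect_identical(inject_dose_effect(sim$cohort, 0), sim$cohort)

  mod <- inject_dose_effect(sim$cohort, extra_sd = 3, window = 14, seed = 49)
  sel <- sim$cohort$scale_id == "part3_off" &
    !is.na(sim$cohort$hours_postdose) & sim$cohort$hours_postdose <= 14
  expect_identical(mod$subtotal[!sel], sim$cohort$subtotal[!sel])
  expect_true(all(mod$subtotal[sel] != sim$cohort$subtotal[sel]))
  added <- mod$subtotal[sel] - sim$cohort$subtotal[sel]
  expect_equal(stats::var(added), 9, tolerance = 0.25 * 9)

  # window below every postdose time changes nothing
  none <- inject_dose_effect(sim$cohort, extra_sd = 3, window = 0.001,
                             seed = 50)
  expect_identical(none$subtotal, sim$cohort$subtotal)
})

test_that("1-year change-score variance follows sigma_dt2 + 2 sigma_e2", {
  sim <- simulate_cohort(generator_config(n_patients = 4000, seed = 51,
                                          scales = "part2",
                                          dropout_hazard = 0))
  ser <- to_monthly_series(sim$cohort, "part2")
  d <- unlist(lapply(ser, function(y) {
    a <- as.character(c(13, 25, 37, 49)); b <- as.character(c(25, 37, 49, 61))
    y[b] - y[a]
  }))
  expect_equal(stats::var(d, na.rm = TRUE), 7.22 + 2 * 3.66,
               tolerance = 0.03)
})
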