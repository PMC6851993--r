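test_that("cohort CSV round-trips and validates its input", {
  coh <- make_fixture_cohort(n = 2, months = c(0, 13))
  expect_equal(nrow(coh), 4L)
  expect_equal(n_patients(coh), 2L)

  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, path)
  back <- read_cohort(path, schedule = attr(coh, "schedule"))
  expect_equal(as.data.frame(back), as.data.frame(coh))

  # empty file with header
  empty <- coh[0, ]
  write_cohort(empty, path)
  expect_equal(nrow(read_cohort(path, schedule = c(0, 13))), 0L)

  # malformed rows are rejected with informative errors
  bad <- as.data.frame(coh)
  bad$item_1 <- c(5, 0, 0, 0)   # out of the 0..4 item range
  expect_error(cohort_table(bad, c(0, 13)), "0..4")
  dup <- rbind(as.data.frame(coh), as.data.frame(coh)[1, ])
  expect_error(cohort_table(dup, c(0, 13)), "duplicate")
  off_grid <- as.data.frame(coh)
  off_grid$month[1] <- 5        # not a scheduled visit
  expect_error(cohort_table(off_grid, c(0, 13)), "schedule")
})

test_that("subtotals are weighted item sums", {
  def33 <- scale_definition("part3", sprintf("it%d", 1:33))
  expect_identical(compute_subtotal(rep(0, 33), def33), 0)
  expect_identical(compute_subtotal(rep(4, 33), def33), 132)

  defw <- scale_definition("f", c("a", "b", "c"), weights = c(0.5, 0.5, 1))
  expect_equal(compute_subtotal(c(1, 2, 3), defw), 4.5)
  expect_error(compute_subtotal(c(1, 2), defw), "3 item scores")

  # unit-weight subtotals are invariant under item permutation
  def <- scale_definition("x", sprintf("it%d", 1:6))
  set.seed(1)
  for (i in 1:10) {
    s <- sample(0:4, 6, replace = TRUE)
    expect_equal(compute_subtotal(s, def), compute_subtotal(sample(s), def))
  }
})

test_that("OFF/ON classification uses strict thresholds", {
  expect_true(classify_off_state(NA_real_, 6))        # untreated
  expect_true(classify_off_state("untreated", 6))
  expect_false(classify_off_state(5.9, 6))
  expect_false(classify_off_state(6, 6))              # boundary fails
  expect_true(classify_off_state(14.5, 14))
  expect_error(classify_off_state(-1, 6), ">= 0")
  expect_error(classify_off_state(8, 0), "positive")

  expect_true(classify_on_state(1, TRUE))
  expect_false(classify_on_state(7, TRUE))
  expect_false(classify_on_state(6, TRUE))            # boundary fails
  expect_false(classify_on_state(1, FALSE))           # untreated has no ON
})

test_that("monthly series carry explicit missings and preserve values", {
  coh <- make_fixture_cohort(n = 1, months = c(0, 13),
                             values = c(5.25, 9.5))
  s <- to_monthly_series(coh, "part2")[[1]]
  expect_length(s, 14)
  expect_equal(sum(is.na(s)), 12)
  expect_identical(unname(s[c(1, 14)]), c(5.25, 9.5))

  single <- make_fixture_cohort(n = 1, months = 0, values = 7)
  expect_length(to_monthly_series(single, "part2")[[1]], 1)

  expect_error(to_monthly_series(coh, "part3_on"), "not present")

  # full PPMI-like schedule: part III OFF values only at annual months
  sim <- simulate_cohort(generator_config(n_patients = 5, seed = 1,
                                          dropout_hazard = 0))
  ser <- to_monthly_series(sim$cohort, "part3_off")
  for (y in ser) {
    obs <- as.integer(names(y))[!is.na(y)]
    expect_true(all(obs %in% c(0, 13, 25, 37, 49, 61)))
  }
  # count of non-missing entries equals count of matching records
  expect_equal(sum(vapply(ser, function(y) sum(!is.na(y)), 0L)),
               sum(sim$cohort$scale_id == "part3_off"))
})
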