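# Construct data whose sample correlation matrix is exactly `R_target`
# (empirically whiten a random matrix, then color by chol(R_target)).
make_exact_cor_data <- function(R_target, n = 200, seed = 1) {
  set.seed(seed)
  p <- ncol(R_target)
  X0 <- matrix(rnorm(n * p), n, p)
  X0 <- scale(X0, center = TRUE, scale = FALSE)
  W <- X0 %*% solve(chol(stats::cov(X0)))
  W %*% chol(R_target)
}

test_that("principal-component extraction matches block closed forms", {
  # two independent blocks of 3 items with within-block r = 0.5:
  # each block's leading eigenvalue is 1 + 2r = 2.0
  R <- diag(6)
  R[1:3, 1:3] <- 0.5; R[4:6, 4:6] <- 0.5; diag(R) <- 1
  X <- make_exact_cor_data(R)
  sol <- extract_factors(X, k = 2, rotation = "none")
  expect_equal(sort(sol$eigenvalues[1:2]), c(2, 2), tolerance = 1e-8)
  expect_equal(sol$combined_explained_variance, 4 / 6, tolerance = 1e-8)

  # full decomposition explains everything
  expect_equal(extract_factors(X, k = 6)$combined_explained_variance, 1,
               tolerance = 1e-9)

  # duplicated item pair loads equally on the single factor
  set.seed(2)
  z <- rnorm(100)
  Xd <- cbind(a = z, b = z, c = rnorm(100))
  sd1 <- extract_factors(Xd, k = 1)
  expect_equal(sd1$loadings["a", 1], sd1$loadings["b", 1],
               tolerance = 1e-9)

  # constant items are named in the error
  Xc <- cbind(u = rnorm(20), v = rep(2, 20))
  expect_error(extract_factors(Xc, k = 1), "v")
  expect_error(extract_factors(X, k = 7), "between 1")
})

test_that("varimax rotation preserves communalities and hits the optimum", {
  set.seed(5)
  for (i in 1:5) {
    L <- matrix(rnorm(14), 7, 2)
    rot <- varimax_rotate(L)
    # orthogonality invariant
    expect_equal(rot %*% t(rot), L %*% t(L), tolerance = 1e-10)
    # criterion matches a brute-force scan over the rotation angle
    angles <- seq(0, pi / 2, by = 1e-4)
    best <- max(vapply(angles, function(a) {
      Rm <- matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2)
      varimax_criterion(L %*% Rm)
    }, 0))
    expect_equal(varimax_criterion(rot), best, tolerance = 1e-6)
  }

  # perfect simple structure is a fixed point (up to sign/permutation)
  Ls <- rbind(c(0.9, 0), c(0.8, 0), c(0, 0.7), c(0, 0.6))
  rot <- varimax_rotate(Ls)
  expect_equal(abs(unname(rot)), abs(Ls), tolerance = 1e-6)

  expect_error(varimax_rotate(matrix(c(1, Inf, 0, 1), 2)), "finite")
  L1 <- matrix(1:3, 3, 1)
  expect_identical(varimax_rotate(L1), L1)
})

test_that("factor scores are loading-weighted item sums", {
  si <- simulate_items(300, seed = 8)
  sol <- extract_factors(si$items, k = 3)
  expect_identical(score_factors(rep(0, 11), sol, 1), 0)
  expect_equal(score_factors(c(2, 0, 1), structure(list(
    loadings = matrix(c(0.8, 0.3, 0.5), 3, 1,
                      dimnames = list(NULL, "F1")),
    item_ids = NULL), class = "factor_solution"), 1), 2.1)
  # unit loadings reduce to the plain subtotal
  unit <- structure(list(loadings = matrix(1, 11, 1), item_ids = NULL),
                    class = "factor_solution")
  s <- si$items[3, ]
  expect_equal(score_factors(unname(s), unit, 1),
               compute_subtotal(unname(s),
                                scale_definition("x", sprintf("i%d", 1:11))))
  expect_error(score_factors(rep(0, 5), sol, 1), "align")
})

test_that("scree eigenvalues behave as a correlation spectrum", {
  set.seed(9)
  X <- matrix(rnorm(20000), 2000, 10)   # independent items
  ev <- scree_eigenvalues(X)
  expect_equal(sum(ev), 10, tolerance = 1e-9)
  expect_true(all(abs(ev - 1) < 0.25))

  # rank-1 signal plus noise: one dominant eigenvalue
  f <- rnorm(300)
  X1 <- outer(f, rep(1, 6)) + 0.3 * matrix(rnorm(1800), 300, 6)
  ev1 <- scree_eigenvalues(X1)
  expect_gt(ev1[1], 4)
  expect_lt(ev1[2], 1)
})

test_that("planted factor structure is recovered from discretized items", {
  si <- simulate_items(5000, seed = 17)
  sol <- extract_factors(si$items, k = 3)
  perm <- apply(abs(stats::cor(si$loadings, sol$loadings)), 1, which.max)
  expect_identical(sort(perm), 1:3)
  aligned <- sol$loadings[, perm]
  aligned <- aligned * rep(sign(colSums(aligned * si$loadings)),
                           each = nrow(aligned))
  expect_lt(max(abs(aligned - si$loadings)), 0.1)

  # scores from the planted solution track the planted latent factors
  planted_sol <- structure(list(loadings = si$loadings, item_ids = NULL),
                           class = "factor_solution")
  for (k in 1:3) {
    sc <- score_factors(si$items, planted_sol, k)
    expect_gt(stats::cor(sc, si$factors[, k]), 0.9)
  }
})
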