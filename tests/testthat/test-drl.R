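test_that("basis of a diagonal covariance is the identity with exact rates", {
  b <- compute_basis(diag(c(4, 1)))
  expect_equal(abs(b$W), diag(2), ignore_attr = TRUE)
  expect_equal(b$contribution, c(80, 20), ignore_attr = TRUE)
  expect_equal(b$lambdas, c(4, 1))
})

test_that("eigenbasis is orthonormal and reproduces the variances exactly", {
  for (seed in c(1, 6)) {
    mix <- random_mixture(seed, N = 4, M = 3)
    b <- compute_basis(mix)
    expect_lt(max(abs(t(b$W) %*% b$W - diag(4))), 1e-10)
    expect_true(all(diff(b$lambdas) <= 1e-12))
    expect_equal(sum(b$contribution), 100)
    # variance of the mixture along w_i equals lambda_i
    for (i in 1:4)
      expect_equal(drop(t(b$W[, i]) %*% mix$sigma %*% b$W[, i]),
                   b$lambdas[i], tolerance = 1e-10)
    # sign convention: largest-magnitude entry of each column is positive
    for (i in 1:4) expect_gt(b$W[which.max(abs(b$W[, i])), i], 0)
  }
  expect_error(compute_basis(matrix(c(1, 2, 0, 1), 2, 2)), "not symmetric")
})

test_that("contribution rates are invariant under node relabeling", {
  mix <- random_mixture(12, N = 4, M = 2)
  perm <- c(4, 2, 1, 3)
  mixp <- drlandscape:::new_mixture(
    mix$weights, mix$means[, perm],
    lapply(mix$sigmas, function(S) S[perm, perm]))
  expect_equal(compute_basis(mixp)$contribution,
               compute_basis(mix)$contribution, tolerance = 1e-10)
})

test_that("symmetric MISA puts PC1 along the anti-diagonal", {
  m <- fixture_misa()
  st <- find_stable_states(m, n_starts = 400, seed = 1)
  # impose the exact symmetric weights so the direction is exact
  st$weights[] <- c(0.5, 0.5)
  mix <- build_mixture(m, st, 0.02)
  b <- compute_basis(mix)
  expect_equal(abs(b$W[, 1]), c(1, 1) / sqrt(2), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_lt(abs(sum(b$W[, 1])), 1e-6)   # entries of opposite sign
})

test_that("full-rank projection is an exact change of variables", {
  mix <- random_mixture(7, N = 3, M = 2)
  b <- compute_basis(mix)
  red <- project_mixture(mix, b, C = 3)
  set.seed(21)
  X <- matrix(stats::runif(60, -1, 3), 20, 3)
  # |W| = 1, so p_z(W'x) = p(x) pointwise
  expect_equal(mixture_density(red, X %*% b$W), mixture_density(mix, X),
               tolerance = 1e-12)
  # projecting then back-rotating is the identity
  expect_equal(project_points(X, b, 3) %*% t(b$W), X, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("C = 1 projection of an axis-aligned Gaussian is its first marginal", {
  sig <- diag(c(0.5, 0.1, 0.02))
  mix <- drlandscape:::new_mixture(1, matrix(c(2, 1, 0), 1, 3), list(sig))
  b <- compute_basis(mix)
  red <- project_mixture(mix, b, C = 1)
  xs <- seq(0, 4, length.out = 31)
  expect_equal(mixture_density(red, matrix(xs, ncol = 1)),
               stats::dnorm(xs, mean = 2, sd = sqrt(0.5)), tolerance = 1e-12)
})

test_that("projected density matches the histogram of projected draws", {
  mix <- random_mixture(9, N = 3, M = 2)
  b <- compute_basis(mix)
  red <- project_mixture(mix, b, C = 2)
  Z <- project_points(sample_mixture(mix, 2e5, seed = 14), b, 2)
  L <- grid_landscape(red, resolution = 24, padding = 2.5, u_cap = 30)
  Lh <- histogram_landscape(Z, L)
  cmp <- compare_landscapes(L, Lh)
  expect_lt(cmp$error, 0.05)
})

test_that("reduced landscapes carry their minima where the states project", {
  m <- fixture_misa()
  st <- find_stable_states(m, n_starts = 400, seed = 1)
  mix <- build_mixture(m, st, 0.02)
  b <- compute_basis(mix)
  L1 <- grid_landscape(project_mixture(mix, b, 1), resolution = 256)
  expect_equal(nrow(L1$minima), 2)
  # equal depth by symmetry (weights differ only by sampling error)
  expect_lt(abs(L1$minima$U[1] - L1$minima$U[2]), 0.1)
  proj <- project_points(st$x, b, 1)
  step <- L1$axes[[1]][2] - L1$axes[[1]][1]
  for (j in 1:2)
    expect_lt(min(abs(L1$minima$PC1 - proj[j])), 1.5 * step)
  # a single Gaussian gives a paraboloid with one minimum at the mean
  mix1 <- drlandscape:::new_mixture(1, matrix(c(1, -1), 1, 2),
                                    list(diag(c(0.2, 0.05))))
  L2 <- grid_landscape(mix1, resolution = 41, padding = 3)
  expect_equal(nrow(L2$minima), 1)
  expect_equal(c(L2$minima$x1, L2$minima$x2), c(1, -1), tolerance = 0.05)
  expect_error(grid_landscape(mix1, resolution = 8), "at least 16")
})

test_that("min_zero shift and the u_cap are recorded and honoured", {
  mix <- random_mixture(2, N = 2, M = 2)
  L <- grid_landscape(mix, resolution = 32, padding = 4, u_cap = 12,
                      shift = "min_zero")
  expect_equal(min(L$U), 0)
  expect_equal(L$shift, "min_zero")
  expect_true(any(L$capped))
  L0 <- grid_landscape(mix, resolution = 32, padding = 4, u_cap = 12)
  expect_equal(L$U, L0$U - min(L0$U), tolerance = 1e-12)
})
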