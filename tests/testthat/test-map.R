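test_that("the discretized action obeys its closed forms", {
  dw <- double_well()
  # resting at a fixed point costs nothing
  rest <- matrix(1, 51, 1)
  expect_equal(path_action(dw, rest, T = 10), 0)
  # a path following the deterministic flow has O(K^-2) residual action
  m <- fixture_misa()
  tr <- ode_trajectory(m, c(0.9, 0.4), times = seq(0, 8, length.out = 201))
  expect_lt(path_action(m, tr[, -1], T = 8), 1e-5)
  # straight-line path under linear decay: hand-computed quadrature
  lin <- custom_model(function(x) -x, function(x) matrix(-1, 1, 1), N = 1,
                      nonneg = FALSE)
  K <- 11; TT <- 2
  path <- matrix(seq(0, 1, length.out = K), K, 1)
  dt <- TT / (K - 1)
  mids <- (path[-1, 1] + path[-K, 1]) / 2
  manual <- 0.5 * dt * sum((1 / TT + mids)^2)   # v = 1/T, f = -x(mid)
  expect_equal(path_action(lin, path, T = TT), manual, tolerance = 1e-14)
  expect_error(path_action(lin, matrix(c(0, NA, 1), 3, 1), T = 1),
               "non-finite")
})

test_that("the action gradient matches finite differences", {
  m <- fixture_misa()
  set.seed(3)
  K <- 9
  p <- matrix(stats::runif(K * 2, 0, 1), K, 2)
  core <- drlandscape:::action_core
  g <- core(m, p, T = 4, want_grad = TRUE)$grad
  h <- 1e-6
  for (idx in list(c(2, 1), c(5, 2), c(8, 1))) {
    pp <- p; pp[idx[1], idx[2]] <- pp[idx[1], idx[2]] + h
    pm <- p; pm[idx[1], idx[2]] <- pm[idx[1], idx[2]] - h
    fd <- (core(m, pp, T = 4)$S - core(m, pm, T = 4)$S) / (2 * h)
    expect_equal(g[idx[1], idx[2]], fd, tolerance = 1e-5)
  }
})

test_that("double-well uphill action reaches the gradient-system value", {
  dw <- double_well()
  mp <- minimize_action(dw, from = -1, to = 0, T = 20, K = 201, seed = 1)
  expect_true(mp$converged)
  # 2 * [V(0) - V(-1)] = 0.5
  expect_equal(mp$action, 2 * (dw_V(0) - dw_V(-1)), tolerance = 0.01)
  # endpoints are pinned
  expect_equal(unname(mp$points[1, 1]), -1)
  expect_equal(unname(mp$points[201, 1]), 0)
})

test_that("minimized actions respect symmetry and feasibility bounds", {
  m <- fixture_misa()
  st <- find_stable_states(m, n_starts = 300, seed = 1)
  f12 <- minimize_action(m, st$x[1, ], st$x[2, ], T = 30, K = 61, seed = 1)
  f21 <- minimize_action(m, st$x[2, ], st$x[1, ], T = 30, K = 61, seed = 1)
  # the swap symmetry of the network forces equal actions
  expect_equal(f12$action, f21$action, tolerance = 1e-3)
  expect_gte(f12$action, 0)
  # doubling T cannot raise the optimum (rest at the endpoint is feasible)
  f12_2T <- minimize_action(m, st$x[1, ], st$x[2, ], T = 60, K = 121,
                            seed = 1)
  expect_lte(f12_2T$action, f12$action + 1e-3)
})

test_that("t_scan warm-starts converge to the quasipotential limit", {
  dw <- double_well()
  tab <- t_scan(dw, -1, 0, T_list = c(5, 10, 20), K = 151, seed = 1)
  expect_equal(nrow(tab), 3)
  expect_true(all(diff(tab$action) <= 1e-3))
  expect_equal(tab$action[3], 0.5, tolerance = 0.01)
  expect_error(t_scan(dw, -1, 0, T_list = c(10, 5), K = 51), "unsorted|incr")
})

test_that("indirect paths cost at least as much as direct ones", {
  m <- fixture_emt_synthetic()
  st <- find_stable_states(m, n_starts = 500, seed = 1)
  lb <- classify_states(st, emt_synthetic_markers())
  pick <- function(l) st$x[which(lb == l), ]
  # compare at matched total time: the two 30-unit legs concatenate to a
  # feasible 60-unit direct path, which warm-starts the direct solve so the
  # optimizer cannot be beaten by its own feasible candidate
  dEA <- minimize_action(m, pick("E"), pick("A"), T = 30, K = 41, seed = 1)
  dAM <- minimize_action(m, pick("A"), pick("M"), T = 30, K = 41, seed = 1)
  dEM <- minimize_action(m, pick("E"), pick("M"), T = 60, K = 81, seed = 1,
                         init = concat_paths(dEA, dAM, K = 81))
  expect_lte(dEM$action, dEA$action + dAM$action + 1e-3)
})

test_that("forward and backward paths differ under non-gradient drift", {
  m <- fixture_emt_synthetic()
  st <- find_stable_states(m, n_starts = 500, seed = 1)
  lb <- classify_states(st, emt_synthetic_markers())
  pick <- function(l) st$x[which(lb == l), ]
  fwd <- minimize_action(m, pick("E"), pick("M"), T = 30, K = 41, seed = 1)
  bwd <- minimize_action(m, pick("M"), pick("E"), T = 30, K = 41, seed = 1)
  rev_bwd <- bwd$points[rev(seq_len(41)), ]
  expect_gt(path_distance(fwd$points, rev_bwd), 0.01)
})

test_that("path distance follows its closed forms and resampling rules", {
  set.seed(6)
  X <- matrix(stats::runif(40), 10, 4)
  expect_equal(path_distance(X, X), 0)
  cvec <- c(0.3, -0.1, 0.2, 0.5)
  Y <- sweep(X, 2, cvec, `+`)
  expect_equal(path_distance(X, Y), 10 * sqrt(sum(cvec^2)) / 4,
               tolerance = 1e-12)
  # unequal point counts are resampled; a resampled identical path is at 0
  expect_equal(path_distance(X, resample_path(X, 25)), 0, tolerance = 1e-12)
  expect_error(path_distance(X, X[, 1:2]), "different state dimensions")
})

test_that("path normalization maps ramps to [0,1] and constants to 0.5", {
  P <- cbind(seq(2, 5, length.out = 11), rep(3, 11), seq(1, 0, length.out = 11))
  Np <- normalize_path(P)
  expect_equal(Np[, 1], seq(0, 1, length.out = 11))
  expect_equal(Np[, 2], rep(0.5, 11))
  expect_equal(Np[, 3], seq(1, 0, length.out = 11))
})

test_that("concatenated legs pass through the junction attractor", {
  dw <- double_well()
  leg1 <- minimize_action(dw, -1, 0, T = 10, K = 41, seed = 1)
  leg2 <- minimize_action(dw, 0, 1, T = 10, K = 41, seed = 1)
  cc <- concat_paths(leg1, leg2, K = 81)
  expect_equal(nrow(cc), 81)
  expect_equal(unname(cc[1, 1]), -1)
  expect_equal(unname(cc[81, 1]), 1)
  expect_lt(min(abs(cc[, 1])), 0.03)
})
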