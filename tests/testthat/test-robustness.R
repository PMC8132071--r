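test_that("a zero-width perturbation range reproduces the reference states", {
  m <- fixture_misa()
  ens <- perturb_and_collect(m, range = c(1, 1), n_sets = 12, seed = 3,
                             n_starts = 120)
  ref <- find_stable_states(m, n_starts = 120, seed = 1)
  expect_equal(length(unique(ens$cluster)), nrow(ref$x))
  expect_equal(nrow(ens$states), 12 * nrow(ref$x))
  for (r in seq_len(nrow(ens$states)))
    expect_lt(min(sqrt(rowSums(sweep(ref$x, 2, ens$states[r, ])^2))), 1e-6)
})

test_that("the ensemble is reproducible under a fixed seed", {
  m <- fixture_misa()
  e1 <- perturb_and_collect(m, range = c(0.9, 1.1), n_sets = 8, seed = 5,
                            n_starts = 100)
  e2 <- perturb_and_collect(m, range = c(0.9, 1.1), n_sets = 8, seed = 5,
                            n_starts = 100)
  expect_identical(e1$states, e2$states)
  expect_identical(e1$factors, e2$factors)
  expect_identical(e1$cluster, e2$cluster)
  # all sampled factors lie inside the requested range
  expect_true(all(e1$factors >= 0.9 & e1$factors <= 1.1))
})

test_that("hierarchical clustering recovers a planted partition", {
  set.seed(8)
  blob <- function(center, n) sweep(matrix(stats::rnorm(n * 3, sd = 0.05),
                                           n, 3), 2, center, `+`)
  X <- rbind(blob(c(1, 0, 0), 20), blob(c(0, 1, 1), 20))
  truth <- rep(1:2, each = 20)
  cl <- drlandscape:::cluster_states(X, 2)
  # agreement up to label switching
  agree <- max(mean(cl == truth), mean(cl == 3 - truth))
  expect_equal(agree, 1)
})

test_that("perturbed quadrastable states cluster into four marker groups", {
  m <- fixture_emt_synthetic()
  ens <- perturb_and_collect(m, range = c(0.75, 1.25), n_sets = 30, seed = 2,
                             n_starts = 150, n_clusters = 4)
  expect_equal(length(unique(ens$cluster)), 4)
  # each cluster's centroid shows one of the four driver patterns
  cents <- do.call(rbind, lapply(1:4, function(k)
    colMeans(ens$states[ens$cluster == k, , drop = FALSE])))
  pat <- paste0(ifelse(cents[, "HIF1s"] > 0.5, "H", "l"),
                ifelse(cents[, "ZEB1s"] > 0.5, "H", "l"))
  expect_setequal(pat, c("ll", "Hl", "lH", "HH"))
  # the 4-group cut separates better than a 2-group cut
  sil4 <- drlandscape:::silhouette_mean(ens$states, ens$cluster)
  sil2 <- drlandscape:::silhouette_mean(
    ens$states, drlandscape:::cluster_states(ens$states, 2))
  expect_gt(sil4, sil2)
})

test_that("zero-width robust-path ensembles repeat the reference path", {
  m <- fixture_misa()
  st <- find_stable_states(m, n_starts = 200, seed = 1)
  rp <- robust_paths(m, st$x[1, ], st$x[2, ], T = 20, K = 31,
                     range = c(1, 1), n_sets = 3, seed = 4, n_starts = 100)
  expect_equal(length(rp$paths), 3)
  expect_lt(path_distance(rp$paths[[1]], rp$paths[[2]]), 1e-4)
  expect_lt(path_distance(rp$paths[[1]], rp$paths[[3]]), 1e-4)
})

test_that("orthogonal projection never increases pointwise path distance", {
  set.seed(9)
  basis <- compute_basis(crossprod(matrix(stats::rnorm(16), 4, 4)) / 4)
  for (i in 1:5) {
    X <- matrix(stats::rnorm(40), 10, 4)
    Y <- matrix(stats::rnorm(40), 10, 4)
    for (C in c(2, 4)) {
      full <- sum(sqrt(rowSums((X - Y)^2)))
      proj <- sum(sqrt(rowSums((project_points(X, basis, C) -
                                project_points(Y, basis, C))^2)))
      expect_lte(proj, full + 1e-12)
    }
  }
})

test_that("sensitivity records are antisymmetric and complete for MISA", {
  m <- fixture_misa()
  st <- find_stable_states(m, n_starts = 150, seed = 1)
  fwd <- global_sensitivity(m, st$x[1, ], st$x[2, ], delta = 0.1,
                            T = 20, K = 41, seed = 1, n_starts = 80)
  # one record per (nonzero link, direction)
  expect_equal(nrow(fwd), 2 * 4)
  expect_true(!any(fwd$flagged))
  bwd <- global_sensitivity(m, st$x[2, ], st$x[1, ], delta = 0.1,
                            T = 20, K = 41, seed = 1, n_starts = 80)
  key <- function(tab) paste(tab$link, tab$direction)
  bwd <- bwd[match(key(fwd), key(bwd)), ]
  expect_equal(fwd$score, -bwd$score, tolerance = 1e-6)
})

test_that("sensitivity sign matches the gradient-system oracle in 1D", {
  # one self-activating gene is a gradient system: V = -integral f dx,
  # and the large-T uphill action is 2 * [V(saddle) - V(start)]
  m1 <- grn_network("g", matrix(1.2), matrix(0), S = 0.5, n = 4, k = 1,
                    g0 = 0.05)
  st <- find_stable_states(m1, n_starts = 100, seed = 1)
  expect_equal(nrow(st$x), 2)
  lo <- st$x[1, ]; hi <- st$x[2, ]
  V_of <- function(model) {
    function(x) -stats::integrate(function(u)
      vapply(u, function(v) drift(model, v), numeric(1)),
      lower = 0, upper = x, rel.tol = 1e-10)$value
  }
  # barriers of a model relative to its *own* attractors (the sensitivity
  # pipeline re-matches endpoints after each perturbation the same way)
  barriers_of <- function(model) {
    own <- find_stable_states(model, n_starts = 60, seed = 2)$x[, 1]
    sad <- stats::uniroot(function(x) drift(model, x),
                          c(own[1] + 1e-3, own[2] - 1e-3))$root
    V <- V_of(model)
    c(up = V(sad) - V(own[1]), down = V(sad) - V(own[2]))
  }
  tab <- global_sensitivity(m1, lo, hi, delta = 0.1, T = 30, K = 81,
                            seed = 1, n_starts = 60)
  expect_equal(nrow(tab), 2)    # one link, two directions
  base <- barriers_of(m1)
  for (r in 1:2) {
    mp <- drlandscape:::apply_factors(m1, 1 + tab$delta[r])
    pert <- barriers_of(mp)
    # analytic change of the uphill barriers under the perturbation
    expect_equal(sign(tab$dS_fwd_pct[r]), sign(pert["up"] - base["up"]),
                 ignore_attr = TRUE)
    expect_equal(sign(tab$dS_bwd_pct[r]), sign(pert["down"] - base["down"]),
                 ignore_attr = TRUE)
  }
})
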