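# Shared fixtures and independent oracles used across the suite.

# 1D double well V = x^4/4 - x^2/2 (f = -V'), the gradient-system oracle
# for the action machinery: large-T uphill action from -1 to 0 is
# 2 * [V(0) - V(-1)] = 0.5.
double_well <- function() {
  custom_model(
    f = function(x) x - x^3,
    jac = function(x) matrix(1 - 3 * x[1]^2, 1, 1),
    N = 1, nonneg = FALSE)
}
dw_V <- function(x) x^4 / 4 - x^2 / 2

# MISA stable fixed points under the default parameters, frozen from an
# independent multistart+Newton root search.
misa_lo_hi <- c(0.0334189652, 0.9665810348)

# central finite-difference Jacobian oracle
fd_jacobian <- function(model, x, h = 1e-6) {
  N <- length(x)
  J <- matrix(0, N, N)
  for (j in seq_len(N)) {
    e <- rep(0, N); e[j] <- h
    J[, j] <- (drift(model, x + e) - drift(model, x - e)) / (2 * h)
  }
  J
}

# a random valid Hill network (seeded); keeps states strictly positive via
# nonzero basal rate
random_network <- function(seed, N = 3) {
  set.seed(seed)
  A <- matrix(0, N, N); B <- matrix(0, N, N)
  for (j in seq_len(N)) for (i in seq_len(N)) {
    r <- stats::runif(1)
    if (r < 0.35) A[j, i] <- stats::runif(1, 0.2, 1)
    else if (r < 0.6) B[j, i] <- stats::runif(1, 0.2, 1)
  }
  grn_network(paste0("n", seq_len(N)), A, B, S = stats::runif(1, 0.3, 0.8),
              n = sample(2:4, 1), k = stats::runif(1, 0.5, 1.5),
              g0 = 0.05)
}

# random stable Jacobian (Hurwitz by construction)
random_hurwitz <- function(seed, N = 4) {
  set.seed(seed)
  M <- matrix(stats::rnorm(N * N), N, N)
  -(M %*% t(M)) / N - diag(N) * 0.5
}

# random Gaussian mixture in N dimensions (positive-definite covariances)
random_mixture <- function(seed, N = 3, M = 2) {
  set.seed(seed)
  w <- stats::runif(M); w <- w / sum(w)
  means <- matrix(stats::runif(M * N, 0, 2), M, N)
  sigmas <- lapply(seq_len(M), function(j) {
    R <- matrix(stats::rnorm(N * N, sd = 0.2), N, N)
    R %*% t(R) + diag(N) * 0.02
  })
  drlandscape:::new_mixture(w, means, sigmas, d = NA_real_,
                            nodes = paste0("x", seq_len(N)))
}

# independent minimax oracle: lowest level at which two cells connect,
# found by thresholding the grid at each candidate level and flood-filling
# (breadth-first, 8-connected) - structurally different from the package's
# sorted-cell union-find.
minimax_oracle_2d <- function(U, a_idx, b_idx) {
  dims <- dim(U)
  levels <- sort(unique(as.vector(U)))
  connected_at <- function(lev) {
    open <- U <= lev
    if (!open[a_idx[1], a_idx[2]] || !open[b_idx[1], b_idx[2]]) return(FALSE)
    seen <- matrix(FALSE, dims[1], dims[2])
    queue <- list(a_idx)
    seen[a_idx[1], a_idx[2]] <- TRUE
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      if (all(cur == b_idx)) return(TRUE)
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        ni <- cur[1] + di; nj <- cur[2] + dj
        if (ni < 1 || nj < 1 || ni > dims[1] || nj > dims[2]) next
        if (open[ni, nj] && !seen[ni, nj]) {
          seen[ni, nj] <- TRUE
          queue[[length(queue) + 1]] <- c(ni, nj)
        }
      }
    }
    FALSE
  }
  for (lev in levels) if (connected_at(lev)) return(lev)
  Inf
}

# wrap a plain matrix as a minimal reduced_landscape for saddle tests
as_landscape_2d <- function(U, u_cap = Inf) {
  axes <- list(x = seq_len(nrow(U)), y = seq_len(ncol(U)))
  L <- structure(list(axes = axes, U = U,
                      capped = matrix(FALSE, nrow(U), ncol(U)),
                      u_cap = u_cap, shift = "none", cell_size = 1,
                      normalization = "mass", C = 2),
                 class = "reduced_landscape")
  L$minima <- drlandscape:::find_local_minima(L)
  L
}
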