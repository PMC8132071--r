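#' Solve the continuous-time algebraic Lyapunov equation
#'
#' Solves `J X + X J' = -Q` for symmetric `X` via the Kronecker-product
#' vectorization `(I (x) J + J (x) I) vec(X) = -vec(Q)`; the result is
#' symmetrized to remove round-off asymmetry. Intended for the moderate
#' dimensions of regulatory-network models (N up to a few dozen).
#'
#' @param J square (Hurwitz) matrix.
#' @param Q symmetric right-hand side.
#' @return symmetric solution matrix.
#' @export
solve_lyapunov <- function(J, Q) {
  N <- nrow(J)
  stopifnot(ncol(J) == N, all(dim(Q) == N))
  M <- kronecker(diag(N), J) + kronecker(J, diag(N))
  X <- matrix(solve(M, -as.vector(Q)), N, N)
  (X + t(X)) / 2
}

#' Stationary covariance of fluctuations around a stable fixed point
#'
#' In the small-noise moment closure the covariance obeys
#' `dSigma/dt = J Sigma + Sigma J' + 2 d I` with `J` the drift Jacobian at
#' the deterministic solution. At a linearly stable fixed point the
#' stationary solution solves the algebraic Lyapunov equation
#' `J Sigma + Sigma J' = -2 d I`, and is symmetric positive definite.
#'
#' @param model a [grn_network()] or [custom_model()].
#' @param x_star stable fixed point (drift vanishes there).
#' @param d diffusion coefficient (> 0).
#' @param method `"lyapunov"` (default) solves the algebraic equation
#'   directly; `"integrate"` integrates the covariance ODE from `Sigma = 0`
#'   until the Frobenius rate of change is negligible — the two agree in the
#'   `t -> Inf` limit, the algebraic route has no integration error.
#' @param t_max,tol_dot horizon and convergence threshold for
#'   `method = "integrate"`.
#' @return N x N symmetric positive-definite covariance matrix.
#' @export
stationary_covariance <- function(model, x_star, d,
                                  method = c("lyapunov", "integrate"),
                                  t_max = 200, tol_dot = 1e-12) {
  method <- match.arg(method)
  stopifnot(d > 0)
  J <- drift_jacobian(model, x_star)
  ev <- eigen(J, only.values = TRUE)$values
  if (max(Re(ev)) >= 0)
    stop("Jacobian has an eigenvalue with non-negative real part (",
         signif(max(Re(ev)), 4),
         "): point is not linearly stable, no positive-definite ",
         "stationary covariance exists")
  N <- nrow(J)
  if (method == "lyapunov") {
    Sg <- solve_lyapunov(J, 2 * d * diag(N))
  } else {
    rhs <- function(t, y, parms) {
      Sg <- matrix(y, N, N)
      dS <- Sg %*% t(J) + J %*% Sg + 2 * d * diag(N)
      list(as.vector(dS))
    }
    times <- seq(0, t_max, length.out = 401)
    out <- deSolve::ode(y = rep(0, N * N), times = times, func = rhs,
                        parms = NULL, rtol = 1e-10, atol = 1e-12)
    Sg <- matrix(out[nrow(out), -1], N, N)
    dS <- Sg %*% t(J) + J %*% Sg + 2 * d * diag(N)
    if (max(abs(dS)) > sqrt(tol_dot))
      warning("covariance ODE not fully stationary at t_max; residual ",
              signif(max(abs(dS)), 3))
    Sg <- (Sg + t(Sg)) / 2
  }
  dimnames(Sg) <- list(model$nodes, model$nodes)
  Sg
}

#' Build the Gaussian-mixture approximation of the steady-state density
#'
#' One Gaussian component per stable state: mean at the fixed point,
#' covariance from [stationary_covariance()], weight equal to the basin
#' weight. The global moments are
#' `mu = sum_j phi_j mu_j` and
#' `Sigma = sum_j phi_j (Sigma_j + mu_j mu_j') - mu mu'`.
#' Components are never pruned, however small their weight, so shallow
#' basins remain visible on the landscape.
#'
#' @param model the network model.
#' @param states a `stable_states` object (see [find_stable_states()]), or a
#'   list with elements `x` (M x N matrix) and `weights`.
#' @param d diffusion coefficient.
#' @param method covariance method, see [stationary_covariance()].
#' @return object of class `gaussian_mixture`: `weights`, `means` (M x N),
#'   `sigmas` (list of N x N), global `mu`, `sigma`, plus `d` and `nodes`.
#' @export
build_mixture <- function(model, states, d, method = "lyapunov") {
  X <- states$x
  w <- as.numeric(states$weights)
  stopifnot(nrow(X) >= 1, length(w) == nrow(X),
            abs(sum(w) - 1) < 1e-8, all(w > 0))
  sigmas <- lapply(seq_len(nrow(X)), function(j)
    stationary_covariance(model, X[j, ], d, method = method))
  new_mixture(w, X, sigmas, d = d, nodes = model$nodes)
}

# assemble a gaussian_mixture and its global moments from parts
new_mixture <- function(weights, means, sigmas, d = NA_real_, nodes = NULL) {
  M <- length(weights); N <- ncol(means)
  nodes <- nodes %||% colnames(means) %||% paste0("x", seq_len(N))
  mu <- as.numeric(weights %*% means)
  sig <- matrix(0, N, N)
  for (j in seq_len(M))
    sig <- sig + weights[j] * (sigmas[[j]] + tcrossprod(means[j, ]))
  sig <- sig - tcrossprod(mu)
  sig <- (sig + t(sig)) / 2
  names(mu) <- nodes; dimnames(sig) <- list(nodes, nodes)
  colnames(means) <- nodes
  structure(list(weights = weights, means = means, sigmas = sigmas,
                 mu = mu, sigma = sig, d = d, nodes = nodes),
            class = "gaussian_mixture")
}

#' @export
print.gaussian_mixture <- function(x, ...) {
  cat("<gaussian_mixture> ", length(x$weights), " component(s) in ",
      length(x$nodes), "D", if (!is.na(x$d)) paste0(", d = ", x$d), "\n",
      sep = "")
  cat("  weights:", paste(signif(x$weights, 4), collapse = ", "), "\n")
  invisible(x)
}

# log density of a multivariate normal, x given as rows
dmvn_log <- function(X, mu, sigma) {
  R <- chol(sigma)
  dev <- sweep(X, 2, mu)
  z <- t(forwardsolve(t(R), t(dev)))  # sigma = R'R, z = R^-T dev'
  -0.5 * rowSums(z^2) - sum(log(diag(R))) - 0.5 * ncol(X) * log(2 * pi)
}

#' Evaluate the mixture probability density
#'
#' `p(x) = sum_j phi_j N(x; mu_j, Sigma_j)`, computed with per-component
#' log-densities and a log-sum-exp reduction for numerical range.
#'
#' @param mix a `gaussian_mixture`.
#' @param x state vector, or matrix with one state per row.
#' @param log return log-density?
#' @return numeric vector of densities (one per row of `x`).
#' @export
mixture_density <- function(mix, x, log = FALSE) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(X) != length(mix$nodes)) stop("state dimension mismatch")
  L <- sapply(seq_along(mix$weights), function(j)
    log(mix$weights[j]) + dmvn_log(X, mix$means[j, ], mix$sigmas[[j]]))
  if (!is.matrix(L)) L <- matrix(L, nrow = nrow(X))
  m <- apply(L, 1, max)
  out <- m + log(rowSums(exp(L - m)))
  if (log) out else exp(out)
}

#' Draw samples from a Gaussian mixture
#' @param mix a `gaussian_mixture`.
#' @param n number of draws.
#' @param seed optional RNG seed.
#' @return n x N matrix of draws.
#' @export
sample_mixture <- function(mix, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  counts <- as.numeric(stats::rmultinom(1, n, mix$weights))
  out <- do.call(rbind, lapply(seq_along(counts), function(j) {
    if (counts[j] == 0) return(NULL)
    MASS::mvrnorm(counts[j], mix$means[j, ], mix$sigmas[[j]])
  }))
  out <- out[sample.int(nrow(out)), , drop = FALSE]
  colnames(out) <- mix$nodes
  out
}

#' Serialize a mixture to JSON
#'
#' Per-component weight, mean and covariance (row-major), plus the global
#' moments and the diffusion coefficient used.
#' @param mix a `gaussian_mixture`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mixture <- function(mix, path) {
  obj <- list(
    nodes = mix$nodes,
    d = if (!is.na(mix$d)) mix$d,
    components = lapply(seq_along(mix$weights), function(j) list(
      weight = mix$weights[j],
      mean = as.numeric(mix$means[j, ]),
      covariance = as.numeric(t(mix$sigmas[[j]])))),
    mu = as.numeric(mix$mu),
    sigma = as.numeric(t(mix$sigma)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a mixture written by [write_mixture()]
#' @param path JSON file.
#' @return a `gaussian_mixture`.
#' @export
read_mixture <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  nodes <- as.character(unlist(obj$nodes))
  N <- length(nodes)
  comps <- obj$components
  w <- vapply(comps, function(cp) as.numeric(cp$weight), numeric(1))
  means <- do.call(rbind, lapply(comps, function(cp)
    as.numeric(unlist(cp$mean))))
  sigmas <- lapply(comps, function(cp)
    matrix(as.numeric(unlist(cp$covariance)), N, N, byrow = TRUE))
  d <- if (is.null(obj$d)) NA_real_ else as.numeric(obj$d)
  new_mixture(w, means, sigmas, d = d, nodes = nodes)
}

#' Component-spread diagnostic for the small-noise approximation
#'
#' The Gaussian-mixture closure assumes basins are well separated relative
#' to the component spread. Reports, for each component pair, the ratio of
#' the mean component standard deviation along the line joining the two
#' means to the inter-mean distance. Values approaching 0.5 signal
#' overlapping components (the diagnostic sets no hard cutoff).
#'
#' @param mix a `gaussian_mixture`.
#' @return data.frame with columns `i`, `j`, `spread_ratio` (empty for a
#'   single component).
#' @export
mixture_overlap_diagnostic <- function(mix) {
  M <- length(mix$weights)
  out <- list()
  if (M >= 2) for (i in 1:(M - 1)) for (j in (i + 1):M) {
    v <- mix$means[j, ] - mix$means[i, ]
    dist <- sqrt(sum(v^2)); u <- v / dist
    si <- sqrt(drop(t(u) %*% mix$sigmas[[i]] %*% u))
    sj <- sqrt(drop(t(u) %*% mix$sigmas[[j]] %*% u))
    out[[length(out) + 1]] <-
      data.frame(i = i, j = j, spread_ratio = (si + sj) / 2 / dist)
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(i = integer(), j = integer(), spread_ratio = numeric())
}
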