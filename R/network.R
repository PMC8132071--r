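#' Construct a Hill-kinetics gene regulatory network model
#'
#' Defines the deterministic drift
#' \deqn{f_i(x) = \sum_j A_{ji} \frac{x_j^n}{S_{ji}^n + x_j^n}
#'              + \sum_j B_{ji} \frac{S_{ji}^n}{S_{ji}^n + x_j^n}
#'              - k_i x_i + g_{0,i}}
#' where `A[j, i]` is the activation strength of node `j` on node `i` and
#' `B[j, i]` the corresponding inhibition strength (a zero entry means no
#' link). Activation uses an increasing Hill function of the regulator level,
#' inhibition a decreasing one; both saturate at the link strength. `k` is
#' first-order degradation and `g0` an optional basal synthesis rate.
#'
#' @param nodes character vector of node identifiers.
#' @param A,B N x N non-negative interaction matrices (source in rows, target
#'   in columns). A given ordered pair may carry an activation or an
#'   inhibition, not both.
#' @param S Hill threshold: a positive scalar (broadcast to every link) or an
#'   N x N matrix of per-link thresholds `S[j, i]`.
#' @param n Hill coefficient (>= 1), controls the steepness of regulation.
#' @param k degradation rate(s): positive scalar or length-N vector.
#' @param g0 basal synthesis rate(s): non-negative scalar or length-N vector.
#' @return An object of class `grn_network`.
#' @seealso [drift()], [drift_jacobian()], [simulate_langevin()],
#'   [read_network()]
#' @export
#' @examples
#' m <- fixture_misa()
#' drift(m, c(0, 0))  # c(0.5, 0.5): only the inhibition terms contribute
grn_network <- function(nodes, A, B, S, n, k, g0 = 0) {
  N <- length(nodes)
  stopifnot(is.character(nodes), N >= 1, !anyDuplicated(nodes))
  A <- as.matrix(A); B <- as.matrix(B)
  if (!all(dim(A) == N) || !all(dim(B) == N))
    stop("A and B must be ", N, " x ", N, " matrices matching length(nodes)")
  if (any(A < 0) || any(B < 0)) stop("interaction strengths must be >= 0")
  if (any(A > 0 & B > 0))
    stop("a (source, target) pair cannot be both activating and inhibiting")
  if (is.matrix(S)) {
    if (!all(dim(S) == N)) stop("matrix S must be N x N")
    if (any(S <= 0)) stop("S must be > 0")
  } else {
    stopifnot(length(S) == 1, S > 0)
  }
  stopifnot(length(n) == 1, n >= 1)
  k <- rep_len(as.numeric(k), N); g0 <- rep_len(as.numeric(g0), N)
  if (any(k <= 0)) stop("k must be > 0")
  if (any(g0 < 0)) stop("g0 must be >= 0")
  dimnames(A) <- dimnames(B) <- list(nodes, nodes)
  structure(
    list(nodes = nodes, A = A, B = B, S = S, n = n, k = k, g0 = g0),
    class = "grn_network")
}

#' @export
print.grn_network <- function(x, ...) {
  cat("<grn_network> ", length(x$nodes), " nodes, ",
      sum(x$A > 0), " activations, ", sum(x$B > 0), " inhibitions\n", sep = "")
  cat("  nodes: ", paste(x$nodes, collapse = ", "), "\n", sep = "")
  cat("  n = ", x$n, ", k = ", paste(unique(x$k), collapse = "/"),
      ", g0 = ", paste(unique(x$g0), collapse = "/"),
      if (!is.matrix(x$S)) paste0(", S = ", x$S) else ", S = <matrix>",
      "\n", sep = "")
  invisible(x)
}

#' Wrap arbitrary drift and Jacobian functions as a model
#'
#' Used for analytically tractable reference systems (e.g. the 1D double-well
#' gradient system) so that the action and path machinery can be validated
#' independently of Hill kinetics.
#'
#' @param f function(x) returning the drift vector; must also accept a matrix
#'   of states (rows) and return a matrix.
#' @param jac function(x) returning the N x N Jacobian of `f` at `x`.
#' @param N state dimension.
#' @param nodes optional names, defaults to x1..xN.
#' @param nonneg clamp states at zero during simulation/optimization?
#' @return An object of class `custom_model`.
#' @export
custom_model <- function(f, jac, N, nodes = paste0("x", seq_len(N)),
                         nonneg = FALSE) {
  stopifnot(is.function(f), is.function(jac), length(nodes) == N)
  structure(list(f = f, jac = jac, nodes = nodes, nonneg = nonneg),
            class = "custom_model")
}

#' Evaluate the deterministic drift f(x)
#'
#' @param model a `grn_network` or `custom_model`.
#' @param x numeric state vector of length N, or an M x N matrix of states
#'   (one per row). Negative components are clamped to 0 before the Hill
#'   terms are evaluated (levels are concentrations).
#' @return drift vector (or M x N matrix, matching the input shape).
#' @export
drift <- function(model, x) UseMethod("drift")

#' @export
drift.custom_model <- function(model, x) model$f(x)

#' @export
drift.grn_network <- function(model, x) {
  vec <- !is.matrix(x)
  X <- if (vec) matrix(x, nrow = 1) else x
  if (ncol(X) != length(model$nodes))
    stop("state dimension ", ncol(X), " does not match network size ",
         length(model$nodes))
  X <- pmax(X, 0)
  n <- model$n
  if (!is.matrix(model$S)) {
    Sn <- model$S^n
    Xn <- X^n
    H <- Xn / (Sn + Xn)          # increasing Hill term per regulator
    F <- H %*% model$A + (1 - H) %*% model$B
  } else {
    # per-link thresholds: assemble target column by column
    F <- matrix(0, nrow(X), ncol(X))
    for (i in seq_len(ncol(X))) {
      Sn <- matrix(model$S[, i]^n, nrow(X), ncol(X), byrow = TRUE)
      Xn <- X^n
      H <- Xn / (Sn + Xn)
      F[, i] <- H %*% model$A[, i] + (1 - H) %*% model$B[, i]
    }
  }
  F <- F - sweep(X, 2, model$k, `*`)
  F <- sweep(F, 2, model$g0, `+`)
  if (vec) as.numeric(F) else F
}

#' Analytic Jacobian of the drift
#'
#' `J[i, j] = d f_i / d x_j`. The diagonal carries the degradation `-k_i`;
#' off-diagonal entries are `(A[j,i] - B[j,i]) * h'(x_j)` with
#' `h'(x) = n S^n x^(n-1) / (S^n + x^n)^2` the Hill derivative (activation
#' and inhibition derivatives differ only in sign).
#'
#' @inheritParams drift
#' @return N x N Jacobian matrix.
#' @export
drift_jacobian <- function(model, x) UseMethod("drift_jacobian")

#' @export
drift_jacobian.custom_model <- function(model, x) model$jac(x)

#' @export
drift_jacobian.grn_network <- function(model, x) {
  N <- length(model$nodes)
  if (length(x) != N) stop("state dimension mismatch")
  x <- pmax(x, 0)
  n <- model$n
  J <- matrix(0, N, N, dimnames = list(model$nodes, model$nodes))
  if (!is.matrix(model$S)) {
    Sn <- model$S^n
    hp <- n * Sn * x^(n - 1) / (Sn + x^n)^2
    hp[x == 0 & n > 1] <- 0
    # contribution of regulator j to target i
    J <- t((model$A - model$B) * hp)   # row i, col j after transpose
  } else {
    for (i in seq_len(N)) {
      Sn <- model$S[, i]^n
      hp <- n * Sn * x^(n - 1) / (Sn + x^n)^2
      hp[x == 0 & n > 1] <- 0
      J[i, ] <- (model$A[, i] - model$B[, i]) * hp
    }
  }
  J - diag(model$k, N)
}

#' Integrate the deterministic ODE
#'
#' Adaptive, stiffness-switching integration (deSolve's `lsoda`) of
#' `dx/dt = f(x)`.
#'
#' @inheritParams drift
#' @param x0 initial state.
#' @param times output times (numeric vector) or a single end time, in which
#'   case 201 equally spaced outputs on `[0, times]` are used.
#' @param ... passed to [deSolve::ode()].
#' @return matrix with a `time` column and one column per node.
#' @export
ode_trajectory <- function(model, x0, times, ...) {
  if (length(times) == 1) times <- seq(0, times, length.out = 201)
  rhs <- function(t, y, parms) list(drift(model, y))
  out <- deSolve::ode(y = x0, times = times, func = rhs, parms = NULL, ...)
  colnames(out) <- c("time", model$nodes)
  unclass(out)
}

#' Simulate Langevin dynamics by Euler-Maruyama
#'
#' Integrates `dx = f(x) dt + sqrt(2 d dt) xi` with independent standard
#' normal increments `xi` per component (Gaussian white noise with
#' `E[G_i(t) G_j(t')] = 2 d delta_ij delta(t - t')`). States are clamped at
#' zero after every step for models with non-negative state (gene levels);
#' many trajectories are advanced in parallel as matrix operations.
#'
#' @inheritParams drift
#' @param d constant homogeneous diffusion coefficient (> 0, or 0 for the
#'   deterministic limit).
#' @param x0 initial state vector, or an `n_traj` x N matrix of per-trajectory
#'   initial states.
#' @param t_end simulated horizon.
#' @param dt Euler-Maruyama step (default 0.01).
#' @param n_traj number of independent trajectories.
#' @param seed RNG seed (optional).
#' @param record_from discard states before this time (burn-in).
#' @param thin record every `thin`-th step.
#' @param clamp clamp states at zero after every step (default for gene
#'   networks, where levels are concentrations). Set `FALSE` when the
#'   simulation serves as a reference for the Gaussian moment closure,
#'   which is defined on the unbounded domain: near a low-expression state
#'   the closure's density extends below zero, and a clamped reference
#'   would differ from it by construction rather than by closure error.
#' @return list of class `langevin_sim` with `times` (recorded times),
#'   `states` (array `n_rec` x N x `n_traj`), `samples` (pooled
#'   `(n_rec * n_traj)` x N matrix), and the configuration used.
#' @export
simulate_langevin <- function(model, d, x0, t_end, dt = 0.01, n_traj = 1,
                              seed = NULL, record_from = 0, thin = 1,
                              clamp = NULL) {
  stopifnot(d >= 0, dt > 0, t_end > dt, n_traj >= 1)
  if (!is.null(seed)) set.seed(seed)
  N <- length(model$nodes)
  X <- if (is.matrix(x0)) {
    stopifnot(ncol(x0) == N)
    matrix(rep(t(x0), length.out = n_traj * N), n_traj, N, byrow = TRUE)
  } else matrix(x0, n_traj, N, byrow = TRUE)
  nonneg <- clamp %||%
    (inherits(model, "grn_network") || isTRUE(model$nonneg))
  n_steps <- ceiling(t_end / dt)
  rec_idx <- seq_len(n_steps)
  rec_idx <- rec_idx[rec_idx * dt >= record_from & rec_idx %% thin == 0]
  states <- array(NA_real_, c(length(rec_idx), N, n_traj))
  sd_step <- sqrt(2 * d * dt)
  ri <- 1
  for (s in seq_len(n_steps)) {
    X <- X + dt * drift(model, X)
    if (d > 0) X <- X + matrix(stats::rnorm(n_traj * N, sd = sd_step), n_traj, N)
    if (nonneg) X <- pmax(X, 0)
    if (!all(is.finite(X)) || max(abs(X)) > 1e8)
      stop("Langevin integration diverged at t = ", round(s * dt, 3),
           "; dt = ", dt, " is too large for this model")
    if (ri <= length(rec_idx) && s == rec_idx[ri]) {
      states[ri, , ] <- t(X)
      ri <- ri + 1
    }
  }
  samples <- matrix(aperm(states, c(1, 3, 2)), ncol = N)
  colnames(samples) <- model$nodes
  structure(list(times = rec_idx * dt, states = states, samples = samples,
                 d = d, dt = dt, n_traj = n_traj, x_final = X),
            class = "langevin_sim")
}

#' @export
print.langevin_sim <- function(x, ...) {
  cat("<langevin_sim> ", nrow(x$samples), " recorded states (",
      x$n_traj, " trajectories), d = ", x$d, ", dt = ", x$dt, "\n", sep = "")
  invisible(x)
}
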