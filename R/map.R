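#' Discretized Freidlin-Wentzell action of a path
#'
#' For a path of K points at uniform times on `[0, T]` with step
#' `dt = T / (K - 1)`, the action
#' \deqn{S = \frac{1}{2}\int_0^T \| \dot x - f(x) \|^2 dt}
#' is discretized segment-wise with midpoint velocities and midpoint drift:
#' `S = (dt / 2) * sum_m || (x_{m+1} - x_m) / dt - f((x_m + x_{m+1}) / 2) ||^2`.
#' This exact formula makes reported actions reproducible bit-for-bit for a
#' given path.
#'
#' @param model the dynamical model (drift + Jacobian).
#' @param path K x N matrix of path points (K >= 3), or a `transition_path`.
#' @param T terminal time (ignored when `path` is a `transition_path`).
#' @return the scalar action (>= 0; zero iff the path follows the drift at
#'   every midpoint).
#' @export
path_action <- function(model, path, T) {
  if (inherits(path, "transition_path")) { T <- path$T; path <- path$points }
  stopifnot(is.matrix(path), nrow(path) >= 3, T > 0)
  if (!all(is.finite(path))) stop("non-finite path values")
  action_core(model, path, T)$S
}

# action + analytic gradient via the chain rule through the discretization
action_core <- function(model, p, T, want_grad = FALSE) {
  K <- nrow(p); N <- ncol(p); dt <- T / (K - 1)
  mid <- (p[-1, , drop = FALSE] + p[-K, , drop = FALSE]) / 2
  v <- (p[-1, , drop = FALSE] - p[-K, , drop = FALSE]) / dt
  fm <- drift(model, mid)
  if (!is.matrix(fm)) fm <- matrix(fm, K - 1, N)
  r <- v - fm
  S <- 0.5 * dt * sum(r^2)
  if (!want_grad) return(list(S = S))
  g <- matrix(0, K, N)
  for (m in seq_len(K - 1)) {
    Jm <- drift_jacobian(model, mid[m, ])
    JTr <- as.numeric(crossprod(Jm, r[m, ]))
    g[m, ]     <- g[m, ]     - r[m, ] - 0.5 * dt * JTr
    g[m + 1, ] <- g[m + 1, ] + r[m, ] - 0.5 * dt * JTr
  }
  list(S = S, grad = g)
}

#' Minimize the transition action between two attractors
#'
#' Quasi-Newton (L-BFGS-B) minimization of the discretized action over the
#' interior path points, endpoints fixed at the two (Newton-polished) fixed
#' points. The initial path is the straight line between the endpoints;
#' additional restarts perturb it with seeded smooth jitter and the best
#' action is kept. For non-negative state models the optimization is
#' box-constrained at zero.
#'
#' @param model the dynamical model.
#' @param from,to endpoint states (length-N vectors), typically rows of
#'   [find_stable_states()]'s `x`.
#' @param T terminal time of the transition.
#' @param K number of path points (default 101).
#' @param n_restarts jittered restarts beyond the straight line (default 3
#'   initializations in total).
#' @param seed RNG seed for the jitter.
#' @param maxit L-BFGS-B iteration cap per start.
#' @param init optional K x N warm-start path overriding the straight line.
#' @param jitter relative amplitude of restart perturbations.
#' @return object of class `transition_path`: `points` (K x N), `T`, `K`,
#'   `action`, `converged`, `from`, `to`.
#' @export
minimize_action <- function(model, from, to, T, K = 101, n_restarts = 3,
                            seed = 1, maxit = 10000, init = NULL,
                            jitter = 0.1) {
  N <- length(from)
  stopifnot(length(to) == N, K >= 3, T > 0)
  nonneg <- inherits(model, "grn_network") || isTRUE(model$nonneg)
  set.seed(seed)
  straight <- outer(seq(0, 1, length.out = K), to - from) +
    matrix(from, K, N, byrow = TRUE)
  inits <- list(if (!is.null(init)) resample_path(init, K) else straight)
  scale <- max(abs(to - from), 1e-3)
  while (length(inits) < max(1, n_restarts)) {
    # smooth random bump, vanishing at the endpoints
    bump <- outer(sin(pi * seq(0, 1, length.out = K)),
                  stats::rnorm(N, sd = jitter * scale))
    cand <- straight + bump
    if (nonneg) cand <- pmax(cand, 0)
    inits[[length(inits) + 1]] <- cand
  }
  obj <- function(par) {
    p <- rbind(from, matrix(par, K - 2, N), to)
    action_core(model, p, T)$S
  }
  grj <- function(par) {
    p <- rbind(from, matrix(par, K - 2, N), to)
    as.vector(action_core(model, p, T, want_grad = TRUE)$grad[
      2:(K - 1), , drop = FALSE])
  }
  best <- NULL
  for (ini in inits) {
    par0 <- as.vector(ini[2:(K - 1), , drop = FALSE])
    o <- stats::optim(par0, obj, grj, method = "L-BFGS-B",
                      lower = if (nonneg) 0 else -Inf,
                      control = list(maxit = maxit, factr = 1e4,
                                     pgtol = 1e-10))
    if (is.null(best) || o$value < best$value) best <- o
  }
  points <- rbind(from, matrix(best$par, K - 2, N), to)
  rownames(points) <- NULL
  colnames(points) <- model$nodes
  structure(list(points = points, T = T, K = K, action = best$value,
                 converged = best$convergence == 0,
                 from = from, to = to),
            class = "transition_path")
}

#' @export
print.transition_path <- function(x, ...) {
  cat("<transition_path> K = ", x$K, ", T = ", x$T,
      ", action = ", signif(x$action, 6),
      if (!x$converged) "  [NOT converged]", "\n", sep = "")
  invisible(x)
}

#' Transition action as a function of terminal time
#'
#' Recomputes the minimum action path for each `T` in increasing order,
#' warm-starting each optimization from the previous optimum. Larger `T`
#' gives tighter (smaller) actions until the quasipotential limit is
#' reached; at fixed K discretization error grows with `T`, which is why
#' the scan reports rather than asserts monotonicity.
#'
#' @inheritParams minimize_action
#' @param T_list increasing vector of terminal times.
#' @return data.frame with columns `T`, `action`, `converged`; the final
#'   path is attached as attribute `"path"`.
#' @export
t_scan <- function(model, from, to, T_list, K = 101, seed = 1, ...) {
  stopifnot(!is.unsorted(T_list, strictly = TRUE))
  rows <- list(); prev <- NULL
  for (TT in T_list) {
    mp <- minimize_action(model, from, to, TT, K = K, seed = seed,
                          init = if (!is.null(prev)) prev$points,
                          n_restarts = if (is.null(prev)) 3 else 1, ...)
    prev <- mp
    rows[[length(rows) + 1]] <-
      data.frame(T = TT, action = mp$action, converged = mp$converged)
  }
  out <- do.call(rbind, rows)
  attr(out, "path") <- prev
  out
}

#' Resample a path to K points by linear interpolation
#' @param path K0 x N matrix or `transition_path`.
#' @param K target number of points.
#' @return K x N matrix.
#' @export
resample_path <- function(path, K) {
  P <- if (inherits(path, "transition_path")) path$points else path
  K0 <- nrow(P)
  if (K0 == K) return(P)
  s0 <- seq(0, 1, length.out = K0)
  s1 <- seq(0, 1, length.out = K)
  apply(P, 2, function(col) stats::approx(s0, col, xout = s1)$y)
}

#' Concatenate two paths sharing an intermediate point
#'
#' Stacks `p1` and `p2` (dropping the duplicated junction point) and
#' resamples to `K` points; used to build indirect paths through an
#' intermediate attractor from two independently minimized legs.
#'
#' @param p1,p2 matrices or `transition_path`s (end of `p1` should equal the
#'   start of `p2`).
#' @param K output point count (defaults to `nrow(p1)`).
#' @return K x N matrix.
#' @export
concat_paths <- function(p1, p2, K = NULL) {
  P1 <- if (inherits(p1, "transition_path")) p1$points else p1
  P2 <- if (inherits(p2, "transition_path")) p2$points else p2
  K <- K %||% nrow(P1)
  resample_path(rbind(P1, P2[-1, , drop = FALSE]), K)
}

#' Euclidean path distance
#'
#' `Dis = (1 / N) * sum_i sqrt(sum_j (x_ij - y_ij)^2)`: the sum over path
#' points of the Euclidean norm of the pointwise difference, divided by the
#' state dimension N. Paths with different point counts are first resampled
#' to the larger count by linear interpolation.
#'
#' @param path_x,path_y K x N matrices (or `transition_path`s) with equal N.
#' @return the scalar distance (0 iff the resampled paths coincide).
#' @export
path_distance <- function(path_x, path_y) {
  X <- if (inherits(path_x, "transition_path")) path_x$points else path_x
  Y <- if (inherits(path_y, "transition_path")) path_y$points else path_y
  if (ncol(X) != ncol(Y)) stop("paths have different state dimensions")
  K <- max(nrow(X), nrow(Y))
  X <- resample_path(X, K); Y <- resample_path(Y, K)
  sum(sqrt(rowSums((X - Y)^2))) / ncol(X)
}

#' Per-component min-max normalization of a path
#'
#' Rescales each component independently to `[0, 1]` along the path (for
#' heatmap display of which components move first along a transition);
#' components constant along the path map to 0.5.
#'
#' @param path K x N matrix or `transition_path`.
#' @param eps range below which a component counts as constant.
#' @return K x N matrix with values in `[0, 1]`.
#' @export
normalize_path <- function(path, eps = 1e-12) {
  P <- if (inherits(path, "transition_path")) path$points else path
  apply(P, 2, function(col) {
    rng <- max(col) - min(col)
    if (rng < eps) rep(0.5, length(col)) else (col - min(col)) / rng
  })
}

#' Write a transition path as TSV plus a JSON summary
#' @param tp a `transition_path`.
#' @param path output TSV (time column then node values); the action, T and
#'   convergence flag go to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_path <- function(tp, path) {
  df <- data.frame(time = seq(0, tp$T, length.out = tp$K), tp$points,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(action = tp$action, T = tp$T, K = tp$K,
                            converged = tp$converged),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
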