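#' Locate all stable fixed points and their basin weights
#'
#' Relaxes the deterministic ODE from `n_starts` initial conditions sampled
#' uniformly in the box `[0, x_max]^N`, Newton-polishes the endpoints with
#' the analytic Jacobian, deduplicates, keeps the linearly stable points, and
#' estimates each basin weight as the fraction of starts attracted to it.
#'
#' The per-node sampling bound defaults to
#' `x_max_i = (sum_j A[j,i] + sum_j B[j,i] + g0_i) / k_i * 1.2`: both Hill
#' terms are bounded by their link strength, so no steady state can exceed
#' this (the inhibition term is a production term saturating at `B[j,i]`
#' when the inhibitor is absent).
#'
#' @param model a [grn_network()].
#' @param n_starts number of random initial conditions (default 1000).
#' @param seed RNG seed for the sampled starts (recorded in the result).
#' @param x_max optional per-node upper sampling bounds (length N or scalar).
#' @param t_relax relaxation horizon per round (fixed-step RK4 batched over
#'   all starts); unconverged starts get up to `max_rounds` further rounds.
#' @param dt_relax RK4 step.
#' @param root_tol fixed points must satisfy `max |f|` below this (1e-8).
#' @param dedup_tol relative L-infinity tolerance for merging polished points.
#' @param stab_tol stability requires all `Re(eig(J)) < -stab_tol`.
#' @param max_rounds relaxation rounds before declaring non-convergence.
#' @return object of class `stable_states`: a list with `x` (M x N matrix,
#'   one stable state per row), `weights` (summing to 1), `jac_eigs` (list of
#'   eigenvalue vectors), `labels`, `n_starts`, `seed`.
#' @export
find_stable_states <- function(model, n_starts = 1000, seed = 1,
                               x_max = NULL, t_relax = 80, dt_relax = 0.02,
                               root_tol = 1e-8, dedup_tol = 1e-4,
                               stab_tol = 1e-9, max_rounds = 6) {
  N <- length(model$nodes)
  stopifnot(n_starts >= 1)
  if (is.null(x_max)) {
    if (!inherits(model, "grn_network"))
      stop("x_max must be given explicitly for custom models")
    x_max <- (colSums(model$A) + colSums(model$B) + model$g0) / model$k * 1.2
    x_max <- pmax(x_max, 1e-3)
  }
  x_max <- rep_len(x_max, N)
  set.seed(seed)
  X <- sapply(x_max, function(u) stats::runif(n_starts, 0, u))
  if (n_starts == 1) X <- matrix(X, 1, N)

  scale <- pmax(x_max, 1e-8)
  accepted <- matrix(numeric(0), 0, N)
  eigs <- list()
  assign_idx <- rep(NA_integer_, n_starts)
  pending <- seq_len(n_starts)

  for (round in seq_len(max_rounds)) {
    X[pending, ] <- rk4_relax(model, X[pending, , drop = FALSE],
                              t_relax, dt_relax)
    # polish distinct endpoints
    reps <- unique(round(sweep(X[pending, , drop = FALSE], 2, scale, `/`), 2))
    for (r in seq_len(nrow(reps))) {
      x0 <- reps[r, ] * scale
      pol <- newton_polish(model, x0, root_tol)
      if (is.null(pol)) next
      ev <- eigen(drift_jacobian(model, pol), only.values = TRUE)$values
      if (max(Re(ev)) >= -stab_tol) next
      if (nrow(accepted) > 0) {
        rel <- apply(abs(sweep(accepted, 2, pol)), 1,
                     function(dd) max(dd / scale))
        if (min(rel) < dedup_tol) next
      }
      accepted <- rbind(accepted, pmax(pol, 0))
      eigs[[nrow(accepted)]] <- ev
    }
    if (nrow(accepted) > 0) {
      d2 <- apply(X[pending, , drop = FALSE], 1, function(xx)
        min(apply(abs(sweep(accepted, 2, xx)), 1, function(dd) max(dd / scale))))
      which_st <- apply(X[pending, , drop = FALSE], 1, function(xx)
        which.min(apply(abs(sweep(accepted, 2, xx)), 1, function(dd) max(dd / scale))))
      ok <- d2 < 0.02
      assign_idx[pending[ok]] <- which_st[ok]
      pending <- pending[!ok]
    }
    if (length(pending) == 0) break
  }
  if (length(pending) > 0)
    stop("no stable state reached from start(s) ",
         paste(utils::head(pending, 10), collapse = ", "),
         if (length(pending) > 10) ", ..." else "",
         " after ", max_rounds, " relaxation rounds ",
         "(possible limit cycle or divergence)")
  if (nrow(accepted) == 0) stop("no stable state found")

  # drop states no start converged to (polishing artefacts), re-index
  used <- sort(unique(assign_idx))
  accepted <- accepted[used, , drop = FALSE]
  eigs <- eigs[used]
  assign_idx <- match(assign_idx, used)
  # order states deterministically by first coordinate, then second, ...
  ord <- do.call(order, as.data.frame(accepted))
  accepted <- accepted[ord, , drop = FALSE]
  eigs <- eigs[ord]
  assign_idx <- match(assign_idx, ord)
  w <- tabulate(assign_idx, nbins = nrow(accepted)) / n_starts
  colnames(accepted) <- model$nodes
  labels <- paste0("state_", seq_len(nrow(accepted)))
  rownames(accepted) <- labels
  structure(list(x = accepted, weights = stats::setNames(w, labels),
                 jac_eigs = stats::setNames(eigs, labels), labels = labels,
                 n_starts = n_starts, seed = seed, nodes = model$nodes),
            class = "stable_states")
}

# batched fixed-step RK4 relaxation toward attractors; X is M x N
rk4_relax <- function(model, X, t_relax, dt) {
  n_steps <- ceiling(t_relax / dt)
  for (s in seq_len(n_steps)) {
    k1 <- drift(model, X)
    k2 <- drift(model, X + dt / 2 * k1)
    k3 <- drift(model, X + dt / 2 * k2)
    k4 <- drift(model, X + dt * k3)
    X <- pmax(X + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4), 0)
    if (!all(is.finite(X))) stop("deterministic relaxation diverged")
  }
  X
}

# damped Newton iteration; returns polished root or NULL
newton_polish <- function(model, x, tol, maxit = 200) {
  for (it in seq_len(maxit)) {
    fx <- drift(model, x)
    if (max(abs(fx)) < tol * 1e-3) break
    J <- drift_jacobian(model, x)
    dx <- tryCatch(solve(J, -fx), error = function(e) NULL)
    if (is.null(dx)) return(NULL)
    step <- 1
    repeat {
      xn <- x + step * dx
      if (max(abs(drift(model, xn))) < max(abs(fx)) || step < 1e-4) break
      step <- step / 2
    }
    if (max(abs(xn - x)) < 1e-15) { x <- xn; break }
    x <- xn
  }
  if (max(abs(drift(model, x))) < tol) x else NULL
}

#' @export
print.stable_states <- function(x, ...) {
  cat("<stable_states> ", nrow(x$x), " stable fixed point(s) from ",
      x$n_starts, " starts (seed ", x$seed, ")\n", sep = "")
  tab <- cbind(round(x$x, 4), weight = round(x$weights, 4))
  print(tab)
  invisible(x)
}

#' @export
as.data.frame.stable_states <- function(x, ...) {
  data.frame(label = x$labels, weight = as.numeric(x$weights),
             as.data.frame(x$x, row.names = NULL), check.names = FALSE)
}

#' Label stable states by marker high/low rules
#'
#' Each rule is a named character vector of `"high"`/`"low"` requirements on
#' node levels, e.g. `list(M = c(HIF1 = "high", ZEB1 = "high"))`. A node
#' counts as "high" in a state when its level exceeds the midpoint of that
#' node's range across all supplied states (the split is data-driven; the
#' underlying biology only fixes qualitative patterns).
#'
#' @param states a `stable_states` object or a numeric matrix of states with
#'   named columns.
#' @param markers named list of rules; empty list labels states
#'   `state_1, state_2, ...`.
#' @return character vector of labels, one per state. States matching no rule
#'   keep their index label and are reported via attribute `"unmatched"`;
#'   if two states receive one label a warning is raised and both are kept
#'   (suffixed `.1`, `.2`, ...).
#' @export
classify_states <- function(states, markers = list()) {
  X <- if (inherits(states, "stable_states")) states$x else as.matrix(states)
  M <- nrow(X)
  labels <- paste0("state_", seq_len(M))
  if (length(markers) == 0) return(labels)
  mk_nodes <- unique(unlist(lapply(markers, names)))
  missing <- setdiff(mk_nodes, colnames(X))
  if (length(missing)) stop("marker rule references unknown node(s): ",
                            paste(missing, collapse = ", "))
  mid <- (apply(X, 2, max) + apply(X, 2, min)) / 2
  high <- sweep(X, 2, mid, `>`)
  unmatched <- integer(0)
  for (s in seq_len(M)) {
    hit <- names(which(vapply(markers, function(rule) {
      all((rule == "high") == high[s, names(rule)])
    }, logical(1))))
    if (length(hit) >= 1) labels[s] <- hit[1] else unmatched <- c(unmatched, s)
  }
  dup <- labels[duplicated(labels)]
  if (length(dup)) {
    warning("states share label(s): ", paste(unique(dup), collapse = ", "),
            "; both reported")
    labels <- make.unique(labels)
  }
  attr(labels, "unmatched") <- unmatched
  labels
}
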