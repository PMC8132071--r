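# --- parameter perturbation machinery -------------------------------------

# indices of the tunable link parameters: nonzero entries of A then B
link_index <- function(model) {
  ia <- which(model$A > 0, arr.ind = TRUE)
  ib <- which(model$B > 0, arr.ind = TRUE)
  data.frame(
    matrix_ = c(rep("A", nrow(ia)), rep("B", nrow(ib))),
    source = model$nodes[c(ia[, 1], ib[, 1])],
    target = model$nodes[c(ia[, 2], ib[, 2])],
    row = c(ia[, 1], ib[, 1]), col = c(ia[, 2], ib[, 2]),
    value = c(model$A[ia], model$B[ib]),
    stringsAsFactors = FALSE)
}

# rebuild the model with per-link multiplicative factors (parallel to
# link_index rows)
apply_factors <- function(model, factors) {
  links <- link_index(model)
  stopifnot(length(factors) == nrow(links))
  A <- model$A; B <- model$B
  for (r in seq_len(nrow(links))) {
    if (links$matrix_[r] == "A")
      A[links$row[r], links$col[r]] <- links$value[r] * factors[r]
    else
      B[links$row[r], links$col[r]] <- links$value[r] * factors[r]
  }
  grn_network(model$nodes, A, B, model$S, model$n, model$k, model$g0)
}

#' Stable states under random parameter perturbation, with clustering
#'
#' Draws `n_sets` parameter sets, each multiplying every nonzero link
#' strength (entries of A and B) by an independent uniform factor in
#' `range`, finds the stable states of each perturbed model, pools them, and
#' hierarchically clusters the pooled state matrix (per-node z-score
#' standardization, Euclidean distance, average linkage) cut at `n_clusters`
#' groups.
#'
#' @param model the reference [grn_network()].
#' @param range fractional perturbation interval, e.g. `c(0.75, 1.25)`.
#' @param n_sets number of parameter sets.
#' @param n_clusters groups to cut the dendrogram into (defaults to the
#'   reference model's stable-state count).
#' @param seed RNG seed (the whole ensemble is reproducible from it).
#' @param n_starts random starts per parameter set for
#'   [find_stable_states()].
#' @return object of class `perturbation_ensemble`: `states` (pooled matrix),
#'   `set_id`, `cluster`, `factors` (n_sets x n_links), `links`, `failed`
#'   (ids of sets with no stable state, skipped), `range`, `seed`.
#' @export
perturb_and_collect <- function(model, range = c(0.75, 1.25), n_sets = 100,
                                n_clusters = NULL, seed = 1, n_starts = 200) {
  stopifnot(length(range) == 2, range[1] <= range[2],
            range[1] > 0, range[2] < 2, n_sets >= 1)
  links <- link_index(model)
  set.seed(seed)
  factors <- matrix(stats::runif(n_sets * nrow(links), range[1], range[2]),
                    n_sets, nrow(links))
  pooled <- list(); set_id <- integer(0); failed <- integer(0)
  for (s in seq_len(n_sets)) {
    pm <- apply_factors(model, factors[s, ])
    st <- tryCatch(
      find_stable_states(pm, n_starts = n_starts, seed = seed + s),
      error = function(e) NULL)
    if (is.null(st)) { failed <- c(failed, s); next }
    pooled[[length(pooled) + 1]] <- st$x
    set_id <- c(set_id, rep(s, nrow(st$x)))
  }
  if (length(failed))
    message(length(failed), " parameter set(s) had no stable state; skipped")
  states <- do.call(rbind, pooled)
  rownames(states) <- NULL
  if (is.null(n_clusters))
    n_clusters <- nrow(find_stable_states(model, n_starts = n_starts,
                                          seed = seed)$x)
  cl <- cluster_states(states, n_clusters)
  structure(list(states = states, set_id = set_id, cluster = cl,
                 factors = factors, links = links, failed = failed,
                 range = range, seed = seed, n_clusters = n_clusters),
            class = "perturbation_ensemble")
}

# z-score columns (constant columns pass through as zero), Euclidean
# distance, average linkage
cluster_states <- function(states, k) {
  Z <- apply(states, 2, function(col) {
    s <- stats::sd(col)
    if (!is.finite(s) || s == 0) rep(0, length(col)) else (col - mean(col)) / s
  })
  if (nrow(states) <= k) return(seq_len(nrow(states)))
  hc <- stats::hclust(stats::dist(Z), method = "average")
  stats::cutree(hc, k = k)
}

#' @export
print.perturbation_ensemble <- function(x, ...) {
  cat("<perturbation_ensemble> ", nrow(x$states), " states from ",
      nrow(x$factors) - length(x$failed), "/", nrow(x$factors),
      " parameter sets in (", x$range[1], ", ", x$range[2], ") x default\n",
      sep = "")
  print(table(cluster = x$cluster))
  invisible(x)
}

# mean silhouette width (Euclidean, on the standardized matrix); internal,
# used to compare cluster-count choices in tests
silhouette_mean <- function(states, labels) {
  Z <- apply(states, 2, function(col) {
    s <- stats::sd(col)
    if (!is.finite(s) || s == 0) rep(0, length(col)) else (col - mean(col)) / s
  })
  D <- as.matrix(stats::dist(Z))
  ks <- sort(unique(labels))
  sil <- vapply(seq_len(nrow(Z)), function(i) {
    own <- labels[i]
    same <- which(labels == own & seq_along(labels) != i)
    if (length(same) == 0) return(0)
    a <- mean(D[i, same])
    b <- min(vapply(setdiff(ks, own), function(kk)
      mean(D[i, labels == kk]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(sil)
}

# match each reference state to the nearest perturbed state (relative L2);
# returns indices into rows of `states`, NA when lost, with an
# ambiguity flag when two candidates are within 10% of each other
match_states <- function(ref, states, ambig_frac = 0.1, lost_tol = 0.5) {
  idx <- integer(nrow(ref)); ambig <- logical(nrow(ref))
  lost <- logical(nrow(ref))
  for (r in seq_len(nrow(ref))) {
    dd <- sqrt(rowSums(sweep(states, 2, ref[r, ])^2)) /
      max(sqrt(sum(ref[r, ]^2)), 1e-12)
    o <- order(dd)
    idx[r] <- o[1]
    ambig[r] <- length(o) > 1 && dd[o[2]] < dd[o[1]] * (1 + ambig_frac)
    lost[r] <- dd[o[1]] > lost_tol
  }
  list(idx = idx, ambiguous = ambig, lost = lost)
}

#' Transition-path ensemble under parameter perturbation
#'
#' For each perturbed parameter set: find the stable states, match the two
#' endpoint attractors to the reference model's (nearest relative-L2 state),
#' and minimize the transition action between them. All collected states are
#' then reduced with PCA (eigendecomposition of the pooled-state covariance)
#' and every path is projected onto the leading components.
#'
#' @inheritParams perturb_and_collect
#' @param from_ref,to_ref reference endpoint states (length-N vectors).
#' @param T,K terminal time and point count for each path.
#' @param range defaults to the tight `c(0.95, 1.05)` used for path
#'   robustness (larger perturbations provoke phase changes).
#' @param C components to keep in the projection.
#' @return list of class `robust_paths`: `paths` (list of K x N matrices),
#'   `projected` (list of K x C), `states` (pooled), `basis`
#'   (`projection_basis` of the pooled states), `skipped` (set ids where an
#'   endpoint was lost or the optimizer failed).
#' @export
robust_paths <- function(model, from_ref, to_ref, T, K = 61,
                         range = c(0.95, 1.05), n_sets = 100, seed = 1,
                         n_starts = 150, C = 2) {
  links <- link_index(model)
  set.seed(seed)
  factors <- matrix(stats::runif(n_sets * nrow(links), range[1], range[2]),
                    n_sets, nrow(links))
  paths <- list(); pooled <- list(); skipped <- integer(0)
  for (s in seq_len(n_sets)) {
    pm <- apply_factors(model, factors[s, ])
    st <- tryCatch(
      find_stable_states(pm, n_starts = n_starts, seed = seed + s),
      error = function(e) NULL)
    if (is.null(st)) { skipped <- c(skipped, s); next }
    mm <- match_states(rbind(from_ref, to_ref), st$x)
    if (any(mm$ambiguous | mm$lost)) { skipped <- c(skipped, s); next }
    mp <- minimize_action(pm, st$x[mm$idx[1], ], st$x[mm$idx[2], ],
                          T = T, K = K, seed = seed + s, n_restarts = 1)
    pooled[[length(pooled) + 1]] <- st$x
    paths[[length(paths) + 1]] <- mp$points
  }
  states <- do.call(rbind, pooled)
  basis <- compute_basis(stats::cov(states))
  projected <- lapply(paths, function(p) project_points(p, basis, C))
  structure(list(paths = paths, projected = projected, states = states,
                 basis = basis, skipped = skipped, range = range,
                 seed = seed),
            class = "robust_paths")
}

#' Corridor summary for an ensemble of direct paths
#'
#' Counts, for each direct path in a [robust_paths()] ensemble, whether it
#' lies nearer (Euclidean path distance) to the indirect corridor through
#' intermediate `via_a` than through `via_b`.
#'
#' @param ensemble a `robust_paths` object.
#' @param via_a_path,via_b_path reference indirect paths (K x N matrices,
#'   e.g. from [concat_paths()]).
#' @return data.frame of per-path distances plus attribute `"n_nearer_a"`.
#' @export
corridor_summary <- function(ensemble, via_a_path, via_b_path) {
  da <- vapply(ensemble$paths, function(p) path_distance(p, via_a_path),
               numeric(1))
  db <- vapply(ensemble$paths, function(p) path_distance(p, via_b_path),
               numeric(1))
  out <- data.frame(dist_via_a = da, dist_via_b = db, nearer_a = da < db)
  attr(out, "n_nearer_a") <- sum(out$nearer_a)
  out
}

#' Link-strength sensitivity of transition actions
#'
#' Perturbs each nonzero entry of A and B by `+delta` and `-delta`
#' individually (the other parameters - thresholds, Hill coefficient,
#' degradation, diffusion - are left untouched), re-finds the two endpoint
#' attractors by nearest relative-L2 match, recomputes the forward and
#' backward transition actions at fixed `T` and `K`, and records the percent
#' change of each relative to the unperturbed actions. The sensitivity
#' score of a record is `dS(to -> from) - dS(from -> to)` in percent; output
#' is sorted by score. Perturbations under which an endpoint disappears (or
#' the match is ambiguous) are flagged `phase_change` and excluded from the
#' ranking order (kept at the end).
#'
#' @param model the reference [grn_network()].
#' @param from_state,to_state reference endpoint states.
#' @param delta fractional perturbation (default 0.10), in (0, 0.5).
#' @param T,K action discretization.
#' @param seed seed for state search and path optimization.
#' @param n_starts starts per state search.
#' @return data.frame with one row per (link, direction): link annotation,
#'   `direction` (+/-), `S_fwd`, `S_bwd`, `dS_fwd_pct`, `dS_bwd_pct`,
#'   `score`, `flagged`.
#' @export
global_sensitivity <- function(model, from_state, to_state, delta = 0.1,
                               T = 40, K = 61, seed = 1, n_starts = 150) {
  stopifnot(delta > 0, delta < 0.5)
  links <- link_index(model)
  base_fwd <- minimize_action(model, from_state, to_state, T, K,
                              seed = seed)$action
  base_bwd <- minimize_action(model, to_state, from_state, T, K,
                              seed = seed)$action
  rows <- list()
  for (r in seq_len(nrow(links))) for (dir in c(+1, -1)) {
    factors <- rep(1, nrow(links))
    factors[r] <- 1 + dir * delta
    pm <- apply_factors(model, factors)
    st <- tryCatch(
      find_stable_states(pm, n_starts = n_starts, seed = seed),
      error = function(e) NULL)
    flagged <- FALSE; Sf <- Sb <- NA_real_
    if (is.null(st)) flagged <- TRUE else {
      mm <- match_states(rbind(from_state, to_state), st$x)
      if (any(mm$ambiguous | mm$lost) || mm$idx[1] == mm$idx[2])
        flagged <- TRUE
      else {
        xf <- st$x[mm$idx[1], ]; xt <- st$x[mm$idx[2], ]
        Sf <- minimize_action(pm, xf, xt, T, K, seed = seed)$action
        Sb <- minimize_action(pm, xt, xf, T, K, seed = seed)$action
      }
    }
    rows[[length(rows) + 1]] <- data.frame(
      link = paste0(links$source[r],
                    if (links$matrix_[r] == "A") " -> " else " -| ",
                    links$target[r]),
      matrix_ = links$matrix_[r], source = links$source[r],
      target = links$target[r], direction = ifelse(dir > 0, "+", "-"),
      delta = dir * delta,
      S_fwd = Sf, S_bwd = Sb,
      dS_fwd_pct = 100 * (Sf - base_fwd) / base_fwd,
      dS_bwd_pct = 100 * (Sb - base_bwd) / base_bwd,
      score = 100 * ((Sb - base_bwd) / base_bwd - (Sf - base_fwd) / base_fwd),
      flagged = flagged, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$flagged, -out$score), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "baseline") <- c(S_fwd = base_fwd, S_bwd = base_bwd)
  out
}
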