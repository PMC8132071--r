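#' Maximal-variance projection basis of a mixture
#'
#' Eigendecomposition of the global mixture covariance. Eigenvalues are
#' sorted descending; the columns of `W` are the corresponding orthonormal
#' eigenvectors (the principal directions of the steady-state density). Each
#' eigenvector's sign is fixed so that its largest-magnitude entry is
#' positive. The contribution rate of PC i is `100 * lambda_i / sum(lambda)`;
#' eigenvalues below `1e-12 * lambda_1` are treated as numerically zero.
#'
#' @param mix a `gaussian_mixture`, or a symmetric covariance matrix.
#' @return object of class `projection_basis`: `W` (N x N), `lambdas`,
#'   `contribution` (percentages summing to 100), `nodes`.
#' @export
compute_basis <- function(mix) {
  sigma <- if (inherits(mix, "gaussian_mixture")) mix$sigma else as.matrix(mix)
  if (max(abs(sigma - t(sigma))) > 1e-8 * max(1, max(abs(sigma))))
    stop("covariance matrix is not symmetric")
  nodes <- colnames(sigma) %||% paste0("x", seq_len(ncol(sigma)))
  e <- eigen((sigma + t(sigma)) / 2, symmetric = TRUE)
  lam <- e$values
  lam[lam < 0 & abs(lam) < 1e-10 * max(lam)] <- 0
  if (any(lam < -1e-10 * max(abs(lam))))
    stop("covariance matrix has a significantly negative eigenvalue")
  W <- e$vectors
  for (i in seq_len(ncol(W))) {
    s <- sign(W[which.max(abs(W[, i])), i])
    if (s < 0) W[, i] <- -W[, i]
  }
  lam_eff <- ifelse(lam < 1e-12 * lam[1], 0, lam)
  contribution <- 100 * lam_eff / sum(lam_eff)
  dimnames(W) <- list(nodes, paste0("PC", seq_along(lam)))
  structure(list(W = W, lambdas = lam, contribution = contribution,
                 nodes = nodes),
            class = "projection_basis")
}

#' @export
print.projection_basis <- function(x, ...) {
  cat("<projection_basis> ", length(x$lambdas), " components\n", sep = "")
  k <- min(5, length(x$lambdas))
  cat("  top contributions (%):",
      paste(sprintf("PC%d=%.2f", seq_len(k), x$contribution[seq_len(k)]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Project a mixture onto the leading principal directions
#'
#' Under `Z = W' X` each component stays Gaussian with mean `W' mu_j` and
#' covariance `W' Sigma_j W`; marginalizing to the first `C` coordinates
#' keeps the leading `C` entries/blocks and the original weights. The
#' reduced density is again a Gaussian mixture.
#'
#' @param mix a `gaussian_mixture`.
#' @param basis a `projection_basis` from [compute_basis()].
#' @param C retained dimension, `1 <= C <= N`.
#' @return a C-dimensional `gaussian_mixture` with nodes `PC1..PCC`.
#' @export
project_mixture <- function(mix, basis, C) {
  N <- length(mix$nodes)
  stopifnot(C >= 1, C <= N)
  Wc <- basis$W[, seq_len(C), drop = FALSE]
  means <- mix$means %*% Wc
  sigmas <- lapply(mix$sigmas, function(S) {
    Sz <- t(Wc) %*% S %*% Wc
    (Sz + t(Sz)) / 2
  })
  new_mixture(mix$weights, means, sigmas, d = mix$d,
              nodes = paste0("PC", seq_len(C)))
}

#' Project points (states or paths) into PC coordinates
#' @param points K x N matrix (or length-N vector) in original coordinates.
#' @param basis a `projection_basis`.
#' @param C number of leading coordinates to keep.
#' @return K x C matrix of projected coordinates.
#' @export
project_points <- function(points, basis, C = 2) {
  P <- if (is.matrix(points)) points else matrix(points, nrow = 1)
  if (ncol(P) != nrow(basis$W)) stop("point dimension mismatch")
  P %*% basis$W[, seq_len(C), drop = FALSE]
}

#' Grid the reduced landscape U = -ln p
#'
#' Evaluates the (reduced) mixture density on a regular grid spanning the
#' component means plus `padding` standard deviations per axis, and converts
#' to potential `U = -ln p`. Cells where the density underflows are capped
#' at `u_cap`. Grid-local minima (strictly lower than all neighbours, below
#' the cap) are located; with default settings each stable state's
#' projection falls in a local-minimum neighbourhood.
#'
#' @param mix a `gaussian_mixture` with 1, 2 or 3 dimensions (project first
#'   with [project_mixture()]).
#' @param resolution grid points per axis (>= 16, default 200).
#' @param padding margin in per-component standard deviations (default 3).
#' @param u_cap potential ceiling where the density underflows (default 50).
#' @param shift `"none"` keeps raw `-ln p`; `"min_zero"` subtracts the grid
#'   minimum so the deepest basin sits at U = 0. Recorded in the result.
#' @return object of class `reduced_landscape`: `axes` (list of coordinate
#'   vectors), `U` (vector / matrix / 3D array), `capped` (logical, same
#'   shape), `minima` (data.frame of grid indices, coordinates and U),
#'   `u_cap`, `shift`, `cell_size`, `normalization = "density"`.
#' @export
grid_landscape <- function(mix, resolution = 200, padding = 3, u_cap = 50,
                           shift = c("none", "min_zero")) {
  shift <- match.arg(shift)
  C <- length(mix$nodes)
  if (!C %in% 1:3) stop("gridding supports 1-3 dimensions, got ", C)
  if (resolution < 16) stop("resolution must be at least 16")
  sds <- sapply(seq_len(C), function(i)
    sqrt(vapply(mix$sigmas, function(S) S[i, i], numeric(1))))
  if (!is.matrix(sds)) sds <- matrix(sds, nrow = 1)
  axes <- lapply(seq_len(C), function(i) {
    lo <- min(mix$means[, i] - padding * sds[, i])
    hi <- max(mix$means[, i] + padding * sds[, i])
    seq(lo, hi, length.out = resolution)
  })
  names(axes) <- mix$nodes
  grid <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
  logp <- mixture_density(mix, grid, log = TRUE)
  U <- pmin(-logp, u_cap)
  capped <- U >= u_cap - 1e-12
  dims <- rep(resolution, C)
  if (C > 1) { dim(U) <- dims; dim(capped) <- dims }
  if (shift == "min_zero") {
    u0 <- min(U)
    U <- U - u0
    u_cap_eff <- u_cap - u0
  } else u_cap_eff <- u_cap
  L <- structure(list(axes = axes, U = U, capped = capped,
                      u_cap = u_cap_eff, shift = shift,
                      cell_size = prod(vapply(axes, function(a) a[2] - a[1],
                                              numeric(1))),
                      normalization = "density", C = C),
                 class = "reduced_landscape")
  L$minima <- find_local_minima(L)
  L
}

# locate local minima on the grid (8-neighbour in 2D, 2 in 1D, 26 in 3D).
# Exact ties (symmetric densities on even grids produce equal-value
# plateaus) are broken by linear index so each plateau yields one minimum;
# capped cells are never minima.
find_local_minima <- function(L) {
  U <- L$U; C <- L$C
  dims <- if (C == 1) length(U) else dim(U)
  offs <- as.matrix(do.call(expand.grid, rep(list(-1:1), C)))
  offs <- offs[rowSums(offs != 0) > 0, , drop = FALSE]
  idx_all <- as.matrix(do.call(expand.grid, lapply(dims, seq_len)))
  is_min <- rep(TRUE, nrow(idx_all))
  Uv <- as.vector(U)
  lin <- function(ix) {
    l <- ix[, 1]
    if (C >= 2) l <- l + (ix[, 2] - 1) * dims[1]
    if (C >= 3) l <- l + (ix[, 3] - 1) * dims[1] * dims[2]
    l
  }
  self_lin <- lin(idx_all)
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(idx_all, 2, offs[r, ], `+`)
    ok <- rep(TRUE, nrow(nb))
    for (cc in seq_len(C)) ok <- ok & nb[, cc] >= 1 & nb[, cc] <= dims[cc]
    cmp <- rep(TRUE, nrow(nb))
    u_self <- Uv[self_lin[ok]]
    nb_lin <- lin(nb[ok, , drop = FALSE])
    u_nb <- Uv[nb_lin]
    cmp[ok] <- u_self < u_nb | (u_self == u_nb & self_lin[ok] < nb_lin)
    is_min <- is_min & cmp
  }
  is_min <- is_min & !as.vector(L$capped)
  sel <- which(is_min)
  ix <- idx_all[sel, , drop = FALSE]
  coords <- vapply(seq_len(C), function(cc)
    L$axes[[cc]][ix[, cc]], numeric(nrow(ix)))
  if (!is.matrix(coords)) coords <- matrix(coords, nrow = nrow(ix), ncol = C)
  out <- data.frame(ix, coords, U = Uv[sel])
  names(out) <- c(paste0("i", seq_len(C)), names(L$axes), "U")
  out[order(out$U), , drop = FALSE]
}

#' @export
print.reduced_landscape <- function(x, ...) {
  cat("<reduced_landscape> ", x$C, "D grid ",
      paste(vapply(x$axes, length, integer(1)), collapse = " x "),
      ", u_cap = ", signif(x$u_cap, 4), ", shift = ", x$shift, "\n", sep = "")
  cat("  ", nrow(x$minima), " local minima\n", sep = "")
  invisible(x)
}

#' Write a landscape grid as delimited text plus a JSON sidecar
#'
#' The grid goes to `<path>` as TSV in long format (one row per cell:
#' coordinates then U); metadata (axes, u_cap, shift, normalization, and
#' optionally the basis) goes to `<path>.json`.
#'
#' @param L a `reduced_landscape`.
#' @param path output TSV path.
#' @param basis optional `projection_basis` to record in the sidecar.
#' @return `path`, invisibly.
#' @export
write_landscape <- function(L, path, basis = NULL) {
  grid <- do.call(expand.grid, c(L$axes, KEEP.OUT.ATTRS = FALSE))
  grid$U <- as.vector(L$U)
  utils::write.table(grid, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(axes = L$axes, u_cap = L$u_cap, shift = L$shift,
               normalization = L$normalization, cell_size = L$cell_size)
  if (!is.null(basis))
    meta$basis <- list(W = as.numeric(t(basis$W)), nodes = basis$nodes,
                       lambdas = basis$lambdas,
                       contribution = basis$contribution)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
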