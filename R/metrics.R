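#' Saddle between two basins by sorted-cell union-find flooding
#'
#' Cells are added in order of increasing potential, each new cell being
#' unioned with its already-flooded neighbours (8-connected in 2D,
#' 2-connected in 1D). The saddle level between two basins is the lowest U
#' at which their sublevel sets merge — the grid minimax over all connected
#' paths; the cell at which the merge happens is the saddle.
#'
#' @param landscape a `reduced_landscape`.
#' @param basin_a,basin_b rows of `landscape$minima` (integer indices into
#'   that data.frame) identifying the two basins.
#' @return list with `U_saddle`, `cell` (grid indices), `coords`,
#'   `bh_a = U_saddle - U_a`, `bh_b = U_saddle - U_b`.
#' @export
find_saddle <- function(landscape, basin_a = 1, basin_b = 2) {
  L <- landscape
  mins <- L$minima
  stopifnot(basin_a %in% seq_len(nrow(mins)), basin_b %in% seq_len(nrow(mins)),
            basin_a != basin_b)
  C <- L$C
  dims <- if (C == 1) length(L$U) else dim(L$U)
  n <- prod(dims)
  Uv <- as.vector(L$U)
  ord <- order(Uv)

  lin_of_min <- function(r) {
    ix <- as.integer(mins[r, seq_len(C)])
    l <- ix[1]
    if (C >= 2) l <- l + (ix[2] - 1) * dims[1]
    if (C >= 3) l <- l + (ix[3] - 1) * dims[1] * dims[2]
    l
  }
  seed_a <- lin_of_min(basin_a); seed_b <- lin_of_min(basin_b)

  parent <- seq_len(n)
  find <- function(i) {
    root <- i
    while (parent[root] != root) root <- parent[root]
    while (parent[i] != root) { nxt <- parent[i]; parent[i] <<- root; i <- nxt }
    root
  }
  # neighbour offsets in linear index space, with column bookkeeping to
  # avoid wrapping across grid edges
  offs <- as.matrix(do.call(expand.grid, rep(list(-1:1), C)))
  offs <- offs[rowSums(offs != 0) > 0, , drop = FALSE]
  mult <- cumprod(c(1, dims))[seq_len(C)]
  coord_of <- function(l) {
    out <- integer(C); l <- l - 1
    for (cc in seq_len(C)) { out[cc] <- l %% dims[cc] + 1; l <- l %/% dims[cc] }
    out
  }
  added <- logical(n)
  merged_at <- NA_real_; merge_cell <- NA_integer_
  for (pos in seq_len(n)) {
    cell <- ord[pos]
    if (Uv[cell] >= L$u_cap - 1e-12) break   # capped plateau: stop flooding
    cix <- coord_of(cell)
    added[cell] <- TRUE
    for (r in seq_len(nrow(offs))) {
      nix <- cix + offs[r, ]
      if (any(nix < 1) || any(nix > dims)) next
      nl <- 1 + sum((nix - 1) * mult)
      if (!added[nl]) next
      ra <- find(cell); rb <- find(nl)
      if (ra != rb) parent[ra] <- rb
      if (added[seed_a] && added[seed_b] &&
          find(seed_a) == find(seed_b)) {
        merged_at <- Uv[cell]; merge_cell <- cell
        break
      }
    }
    if (!is.na(merged_at)) break
  }
  if (is.na(merged_at))
    stop("basins never merge below the potential cap (u_cap = ",
         signif(L$u_cap, 4), "): basins separated above cap")
  cix <- coord_of(merge_cell)
  coords <- vapply(seq_len(C), function(cc) L$axes[[cc]][cix[cc]], numeric(1))
  list(U_saddle = merged_at, cell = cix, coords = coords,
       bh_a = merged_at - mins$U[basin_a], bh_b = merged_at - mins$U[basin_b])
}

#' Barrier-height report for a gridded landscape
#'
#' For every pair of local minima: the minimax saddle level, the barrier
#' height out of each basin (`BH = U_saddle - U_stable`, always >= 0), and
#' the signed relative barrier height `RBH = U_a - U_b` (potential
#' difference between the two minima; antisymmetric in the pair).
#'
#' @param landscape a `reduced_landscape` with >= 2 local minima.
#' @return data.frame with one row per unordered pair.
#' @export
barrier_heights <- function(landscape) {
  M <- nrow(landscape$minima)
  if (M < 2) stop("need at least two basins to compute barriers")
  rows <- list()
  for (a in 1:(M - 1)) for (b in (a + 1):M) {
    sd <- find_saddle(landscape, a, b)
    rows[[length(rows) + 1]] <- data.frame(
      basin_a = a, basin_b = b, U_saddle = sd$U_saddle,
      U_a = landscape$minima$U[a], U_b = landscape$minima$U[b],
      bh_a = sd$bh_a, bh_b = sd$bh_b,
      rbh = landscape$minima$U[a] - landscape$minima$U[b])
  }
  do.call(rbind, rows)
}

#' Reference landscape from simulation samples
#'
#' Bins samples on the grid of an existing landscape (or explicit axes) and
#' sets `U = -ln(mass)` with `mass` the fraction of samples per cell. Empty
#' cells are capped at `u_cap`. The result is on the probability-mass scale
#' (`normalization = "mass"`); a density-based landscape on a uniform grid
#' differs only by the additive constant `-ln(cell size)`, which
#' [compare_landscapes()] reconciles automatically.
#'
#' @param samples K x C matrix of simulated (already projected, if needed)
#'   states.
#' @param landscape optional `reduced_landscape` whose grid to reuse.
#' @param axes explicit list of grid-centre vectors (if no landscape given).
#' @param u_cap cap for empty cells (defaults to the template's).
#' @return a `reduced_landscape` with `normalization = "mass"`.
#' @export
histogram_landscape <- function(samples, landscape = NULL, axes = NULL,
                                u_cap = NULL) {
  if (is.null(axes)) {
    if (is.null(landscape)) stop("give either a template landscape or axes")
    axes <- landscape$axes
  }
  u_cap <- u_cap %||% (landscape$u_cap %||% 50)
  S <- if (is.matrix(samples)) samples else matrix(samples, ncol = 1)
  C <- length(axes)
  if (ncol(S) != C) stop("sample dimension does not match the grid")
  dims <- vapply(axes, length, integer(1))
  edges <- lapply(axes, function(a) {
    h <- (a[2] - a[1]) / 2
    c(a - h, a[length(a)] + h)
  })
  idx <- matrix(0L, nrow(S), C)
  keep <- rep(TRUE, nrow(S))
  for (cc in seq_len(C)) {
    idx[, cc] <- findInterval(S[, cc], edges[[cc]], rightmost.closed = TRUE)
    keep <- keep & idx[, cc] >= 1 & idx[, cc] <= dims[cc]
  }
  idx <- idx[keep, , drop = FALSE]
  mult <- cumprod(c(1, dims))[seq_len(C)]
  lin <- 1 + as.vector((idx - 1) %*% mult)
  counts <- tabulate(lin, nbins = prod(dims))
  mass <- counts / nrow(S)    # normalized over all samples incl. off-grid
  U <- ifelse(mass > 0, -log(mass), u_cap)
  U <- pmin(U, u_cap)
  capped <- U >= u_cap - 1e-12
  if (C > 1) { dim(U) <- dims; dim(capped) <- dims }
  L <- structure(list(axes = axes, U = U, capped = capped, u_cap = u_cap,
                      shift = "none",
                      cell_size = prod(vapply(axes, function(a) a[2] - a[1],
                                              numeric(1))),
                      normalization = "mass", C = C,
                      n_samples = nrow(S), n_retained = sum(keep)),
                 class = "reduced_landscape")
  L$minima <- find_local_minima(L)
  L
}

# put a landscape's U on the probability-mass scale
as_mass_scale <- function(L) {
  if (L$normalization == "mass") return(L)
  if (L$shift != "none")
    stop("cannot rescale a shifted landscape; rebuild with shift = 'none'")
  shiftc <- -log(L$cell_size)
  L$U <- ifelse(as.vector(L$capped), L$u_cap + shiftc,
                as.vector(L$U) + shiftc)
  dims <- vapply(L$axes, length, integer(1))
  if (L$C > 1) dim(L$U) <- dims
  L$u_cap <- L$u_cap + shiftc
  if (!is.null(L$minima) && nrow(L$minima) > 0)
    L$minima$U <- L$minima$U + shiftc
  L$normalization <- "mass"
  L
}

#' Relative error and barrier correlation between two landscapes
#'
#' Mean relative deviation over jointly valid cells,
#' `error = mean(|U_1 - U_2| / U_2)`, with both landscapes first placed on
#' the probability-mass scale so U is strictly positive and the ratio well
#' defined. Cells capped (zero estimated density) in either landscape are
#' excluded. The unnormalized sum of ratios is also returned.
#'
#' @param L1 landscape under test (e.g. the moment-closure landscape).
#' @param L2 reference landscape (e.g. from Langevin simulation), same grid.
#' @return list with `error` (mean ratio), `error_sum` (plain sum),
#'   `n_valid` (cells compared).
#' @export
compare_landscapes <- function(L1, L2) {
  if (!identical(vapply(L1$axes, length, integer(1)),
                 vapply(L2$axes, length, integer(1))) ||
      max(abs(unlist(L1$axes) - unlist(L2$axes))) > 1e-9)
    stop("landscapes are on different grids")
  A <- as_mass_scale(L1); B <- as_mass_scale(L2)
  valid <- !as.vector(A$capped) & !as.vector(B$capped)
  if (!any(valid)) stop("no jointly valid (uncapped) cells to compare")
  ua <- as.vector(A$U)[valid]; ub <- as.vector(B$U)[valid]
  ratios <- abs(ua - ub) / abs(ub)
  list(error = mean(ratios), error_sum = sum(ratios), n_valid = sum(valid))
}

#' Pearson correlation between two barrier-height series
#'
#' Convenience wrapper for parameter sweeps: given per-sweep barrier tables
#' from two landscape estimates (e.g. moment closure vs simulation), returns
#' the Pearson correlation of the pooled `bh_a`/`bh_b` values.
#'
#' @param bh1,bh2 data.frames from [barrier_heights()] (or vectors).
#' @return Pearson correlation coefficient.
#' @export
barrier_correlation <- function(bh1, bh2) {
  v1 <- if (is.data.frame(bh1)) c(bh1$bh_a, bh1$bh_b) else as.numeric(bh1)
  v2 <- if (is.data.frame(bh2)) c(bh2$bh_a, bh2$bh_b) else as.numeric(bh2)
  stopifnot(length(v1) == length(v2))
  stats::cor(v1, v2)
}
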