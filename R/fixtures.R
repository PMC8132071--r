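#' The mutual-inhibition self-activation (MISA) two-gene switch
#'
#' The canonical bistable cell-fate motif: two genes, each activating itself
#' (strength `a`) and inhibiting the other (strength `b`). Defaults:
#' `a = 0.5, b = 0.5, S = 0.5, n = 4, k = 1`, which give two stable states,
#' mirror images of each other under coordinate swap.
#'
#' The attached attribute `"d_default"` (0.02) is the package's frozen
#' diffusion coefficient for this fixture, calibrated once against the
#' mixture's leading contribution rate (see the methods vignette).
#'
#' @param a self-activation strength.
#' @param b mutual-inhibition strength.
#' @param S,n,k,g0 Hill threshold, Hill coefficient, degradation, basal rate.
#' @return a [grn_network()] with nodes `g1`, `g2`.
#' @export
#' @examples
#' find_stable_states(fixture_misa(), n_starts = 200, seed = 1)
fixture_misa <- function(a = 0.5, b = 0.5, S = 0.5, n = 4, k = 1, g0 = 0) {
  A <- diag(a, 2)
  B <- matrix(c(0, b, b, 0), 2, 2)
  m <- grn_network(c("g1", "g2"), A, B, S = S, n = n, k = k, g0 = g0)
  attr(m, "d_default") <- 0.02
  m
}

#' Synthetic multistable self-activation ring
#'
#' `n_nodes` self-activating genes arranged on a ring, each inhibiting its
#' two neighbours (for `n_nodes = 2` this is exactly the MISA topology).
#' With the frozen parameters `a = 1, b = 0.5, S = 0.5, n = 4, k = 1` the
#' number of stable states grows with the number of positive-feedback
#' loops: 3, 4, 7, 11, 18 states for 2..6 nodes (the 4-node fixture has
#' seven: four single-high states, two opposite-pair states, and the
#' all-intermediate state).
#'
#' @param n_nodes ring size, between 2 and 6.
#' @param a,b,S,n,k frozen fixture parameters; override only for
#'   exploration.
#' @return a [grn_network()] with nodes `g1..g<n_nodes>`.
#' @export
fixture_synthetic_multistable <- function(n_nodes = 4, a = 1, b = 0.5,
                                          S = 0.5, n = 4, k = 1) {
  stopifnot(n_nodes >= 2, n_nodes <= 6)
  N <- n_nodes
  A <- diag(a, N)
  B <- matrix(0, N, N)
  if (N == 2) B <- matrix(c(0, b, b, 0), 2, 2)
  else for (i in seq_len(N)) {
    B[(i %% N) + 1, i] <- b
    B[((i - 2) %% N) + 1, i] <- b
  }
  grn_network(paste0("g", seq_len(N)), A, B, S = S, n = n, k = k)
}

#' Synthetic quadrastable metabolism/EMT-style switch (synthetic stand-in)
#'
#' A four-node model built from two coupled toggle switches, emulating the
#' qualitative structure of metabolism-EMT crosstalk: a metabolic toggle
#' (`HIF1s` vs `AMPKs`, mutual inhibition + self-activation) and an EMT
#' toggle (`ZEB1s` vs `MIR200s`), with a weak activation of the EMT driver
#' by the metabolic driver (`HIF1s -> ZEB1s`). The four stable states map
#' onto epithelial-like (both drivers low), abnormal-metabolic-like (HIF1s
#' high only), hybrid-like (ZEB1s high only) and mesenchymal-like (both
#' high) expression patterns; the coupling makes the metabolic switch flip
#' first along the low-to-high transition corridor.
#'
#' This network is a synthetic construction for exercising the pipeline
#' end to end (state classification, clustering, transition paths); it is
#' not a transcription of any published metabolism-EMT parameterization,
#' and node names carry an `s` suffix ("synthetic") as a reminder.
#'
#' @param coupling strength of the HIF1s -> ZEB1s activation (default 0.1).
#' @return a [grn_network()] with nodes `HIF1s`, `AMPKs`, `ZEB1s`, `MIR200s`.
#' @export
fixture_emt_synthetic <- function(coupling = 0.1) {
  nodes <- c("HIF1s", "AMPKs", "ZEB1s", "MIR200s")
  A <- matrix(0, 4, 4, dimnames = list(nodes, nodes))
  B <- matrix(0, 4, 4, dimnames = list(nodes, nodes))
  diag(A) <- 0.5                       # self-activations
  B["HIF1s", "AMPKs"] <- 0.5; B["AMPKs", "HIF1s"] <- 0.5
  B["ZEB1s", "MIR200s"] <- 0.5; B["MIR200s", "ZEB1s"] <- 0.5
  A["HIF1s", "ZEB1s"] <- coupling      # metabolism drives EMT, weakly
  m <- grn_network(nodes, A, B, S = 0.5, n = 4, k = 1)
  attr(m, "d_default") <- 0.02
  m
}

#' Marker rules for the synthetic quadrastable fixture
#' @return named list of high/low rules for [classify_states()]: `E`
#'   (HIF1s low, ZEB1s low), `A` (HIF1s high, ZEB1s low), `H` (HIF1s low,
#'   ZEB1s high), `M` (both high).
#' @export
emt_synthetic_markers <- function() {
  list(E = c(HIF1s = "low",  ZEB1s = "low"),
       A = c(HIF1s = "high", ZEB1s = "low"),
       H = c(HIF1s = "low",  ZEB1s = "high"),
       M = c(HIF1s = "high", ZEB1s = "high"))
}

#' Run the landscape pipeline end to end
#'
#' fixpoints -> mixture -> basis -> reduced landscape (-> barriers), writing
#' all outputs plus a manifest to `out_dir`. The manifest echoes the full
#' configuration, seeds and package version, which suffices to reproduce
#' every output exactly.
#'
#' @param config named list (or YAML/JSON path) with entries:
#'   `network` (edge-list TSV path) and `params` (config list/path), or
#'   `fixture` (one of `"misa"`, `"synthetic4"`, `"emt_synthetic"`);
#'   `d` (diffusion coefficient; falls back to the network's default);
#'   `seed` (default 1); `n_starts` (default 1000); `pcs` (reduced
#'   dimension, default 2, capped at N); `resolution`, `padding`, `u_cap`
#'   (grid options); `out_dir` (required).
#' @return invisibly, a list with the computed objects (`states`, `mixture`,
#'   `basis`, `landscape`, `barriers`) and the manifest.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) read_params(config) else config
  if (is.null(cfg$out_dir)) stop("config must name an out_dir")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  model <- stage("network", {
    if (!is.null(cfg$fixture)) switch(cfg$fixture,
      misa = fixture_misa(),
      synthetic4 = fixture_synthetic_multistable(4),
      emt_synthetic = fixture_emt_synthetic(),
      stop("unknown fixture '", cfg$fixture, "'"))
    else read_network(cfg$network, cfg$params)
  })
  d <- cfg$d %||% attr(model, "d_default") %||%
    stop("no diffusion coefficient: set d in the config")
  seed <- cfg$seed %||% 1
  states <- stage("fixpoints",
    find_stable_states(model, n_starts = cfg$n_starts %||% 1000,
                       seed = seed))
  utils::write.table(
    as.data.frame(states), file.path(cfg$out_dir, "states.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  mixture <- stage("tme", build_mixture(model, states, d))
  write_mixture(mixture, file.path(cfg$out_dir, "mixture.json"))
  basis <- stage("drl", compute_basis(mixture))
  C <- min(cfg$pcs %||% 2, length(model$nodes))
  landscape <- stage("landscape", grid_landscape(
    project_mixture(mixture, basis, C),
    resolution = cfg$resolution %||% 200,
    padding = cfg$padding %||% 3,
    u_cap = cfg$u_cap %||% 50))
  write_landscape(landscape, file.path(cfg$out_dir, "landscape.tsv"),
                  basis = basis)
  barriers <- NULL
  if (nrow(landscape$minima) >= 2) {
    barriers <- stage("barriers", barrier_heights(landscape))
    utils::write.table(barriers, file.path(cfg$out_dir, "barriers.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- list(
    config = cfg, d = d, seed = seed,
    n_states = nrow(states$x), weights = as.numeric(states$weights),
    contribution = basis$contribution,
    package_version = as.character(utils::packageVersion("drlandscape")),
    r_version = R.version.string)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(model = model, states = states, mixture = mixture,
                 basis = basis, landscape = landscape, barriers = barriers,
                 manifest = manifest))
}
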