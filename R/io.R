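#' Read a network from an edge-list TSV plus a parameter config
#'
#' The canonical network format is a UTF-8 tab-separated file with a header
#' row and columns `source`, `target`, `sign` (one of `activate`/`inhibit`)
#' and `strength`. A blank (or `NA`) strength falls back to the global
#' default `a` (activations) or `b` (inhibitions) from the config. Node names
#' are taken from the config if given, otherwise from the union of sources
#' and targets in file order.
#'
#' @param path path to the edge-list TSV.
#' @param config either a named list or a path to a YAML/JSON file with keys
#'   `S`, `n`, `k` and optionally `g0`, `a`, `b`, `nodes`, `d`. `S` may be a
#'   scalar or, for per-link thresholds, a list of `source target value`
#'   triples under key `S_links` with scalar `S` as the fallback.
#' @return a validated [grn_network()]. The config's diffusion coefficient
#'   `d`, if present, is attached as attribute `"d_default"`.
#' @export
read_network <- function(path, config) {
  if (!file.exists(path)) stop("network file not found: ", path)
  cfg <- if (is.character(config)) read_params(config) else config
  for (key in c("S", "n", "k")) if (is.null(cfg[[key]]))
    stop("config is missing required key '", key, "'")
  edges <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("source", "target", "sign")
  if (!all(need %in% names(edges)))
    stop("edge list must have columns source, target, sign (and strength)")
  if (!"strength" %in% names(edges)) edges$strength <- NA
  if (nrow(edges) > 0 && anyDuplicated(edges[, c("source", "target")]))
    stop("duplicate (source, target) rows in ", path)
  bad <- setdiff(unique(edges$sign), c("activate", "inhibit"))
  if (length(bad)) stop("unknown sign value(s): ", paste(bad, collapse = ", "))
  nodes <- cfg$nodes %||% unique(c(edges$source, edges$target))
  nodes <- as.character(nodes)
  unknown <- setdiff(unique(c(edges$source, edges$target)), nodes)
  if (length(unknown)) stop("unknown node name(s): ",
                            paste(unknown, collapse = ", "))
  N <- length(nodes)
  A <- B <- matrix(0, N, N, dimnames = list(nodes, nodes))
  str <- suppressWarnings(as.numeric(as.character(edges$strength)))
  act <- edges$sign == "activate"
  str[is.na(str) & act]  <- cfg$a %||% NA
  str[is.na(str) & !act] <- cfg$b %||% NA
  if (anyNA(str) && nrow(edges) > 0)
    stop("blank strength with no global default a/b in config")
  if (any(str < 0, na.rm = TRUE)) stop("negative strength in ", path)
  for (r in seq_len(nrow(edges))) {
    j <- edges$source[r]; i <- edges$target[r]
    if (act[r]) A[j, i] <- str[r] else B[j, i] <- str[r]
  }
  S <- cfg$S
  if (!is.null(cfg$S_links)) {
    Sm <- matrix(as.numeric(S), N, N, dimnames = list(nodes, nodes))
    for (tr in cfg$S_links) Sm[tr[[1]], tr[[2]]] <- as.numeric(tr[[3]])
    S <- Sm
  }
  model <- grn_network(nodes, A, B, S = S, n = cfg$n, k = cfg$k,
                       g0 = cfg$g0 %||% 0)
  if (!is.null(cfg$d)) attr(model, "d_default") <- cfg$d
  model
}

#' Read a parameter config (YAML or JSON)
#' @param path file path; format chosen by extension (.json vs .yml/.yaml).
#' @return named list.
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  # YAML 1.1 parses a bare `n`/`y` key as a boolean; map it back, since
  # `n` (the Hill coefficient) is a core parameter name
  names(cfg)[names(cfg) == "FALSE"] <- "n"
  names(cfg)[names(cfg) == "TRUE"] <- "y"
  cfg
}

#' Write a network to the edge-list TSV format
#' @param model a [grn_network()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_network <- function(model, path) {
  rows <- list()
  for (j in seq_along(model$nodes)) for (i in seq_along(model$nodes)) {
    if (model$A[j, i] > 0)
      rows[[length(rows) + 1]] <- data.frame(
        source = model$nodes[j], target = model$nodes[i],
        sign = "activate", strength = model$A[j, i])
    if (model$B[j, i] > 0)
      rows[[length(rows) + 1]] <- data.frame(
        source = model$nodes[j], target = model$nodes[i],
        sign = "inhibit", strength = model$B[j, i])
  }
  edges <- if (length(rows)) do.call(rbind, rows) else
    data.frame(source = character(), target = character(),
               sign = character(), strength = numeric())
  utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
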