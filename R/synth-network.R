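#' Generate an interaction network with planted communities, plus gene sets
#'
#' Draws a stochastic-block-model graph over \code{n_network_genes}: genes
#' inside a planted community are connected with probability
#' \code{p_within}, all other pairs with \code{p_between}; genes beyond the
#' community sizes are background. Gene sets aligned to the communities are
#' emitted alongside random decoy sets (including one decoy made of genes
#' absent from the graph, for null-calibration checks).
#'
#' @param config \code{\link{simulation_config}}.
#' @return list: \code{edges} (data.frame from/to), \code{genes} (all node
#'   names, including isolated ones), \code{sets} (named list for GMT
#'   output), \code{truth} (named vector gene -> community id; background
#'   genes = 0).
#' @export
generate_network_and_sets <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$p_within < config$p_between) {
    warning("p_within < p_between: planted modules will not be recoverable")
  }
  set.seed(config$seed + 3L)
  n <- config$n_network_genes
  sizes <- config$community_sizes
  n_bg <- n - sum(sizes)
  block_sizes <- c(sizes, if (n_bg > 0) rep(1L, 0))
  membership <- c(rep(seq_along(sizes), times = sizes), rep(0L, n_bg))
  genes <- sprintf("NG%04d", seq_len(n))
  names(membership) <- genes

  pm <- matrix(config$p_between, length(sizes) + (n_bg > 0),
               length(sizes) + (n_bg > 0))
  diag(pm)[seq_along(sizes)] <- config$p_within
  if (n_bg > 0) pm[nrow(pm), ncol(pm)] <- config$p_between
  g <- igraph::sample_sbm(n, pref.matrix = pm,
                          block.sizes = c(sizes, if (n_bg > 0) n_bg))
  igraph::V(g)$name <- genes
  el <- igraph::as_edgelist(g)
  edges <- data.frame(from = el[, 1], to = el[, 2], stringsAsFactors = FALSE)

  sets <- lapply(seq_along(sizes), function(k) genes[membership == k])
  names(sets) <- sprintf("community%02d", seq_along(sizes))
  n_decoy <- 3L
  for (d in seq_len(n_decoy)) {
    sets[[sprintf("decoy%02d", d)]] <- sample(genes, min(20L, n))
  }
  sets[["decoy_absent"]] <- sprintf("ABSENT%03d", 1:10)
  list(edges = edges, genes = genes, sets = sets, truth = membership)
}

#' Write gene sets to a GMT file
#' @param sets named list of gene vectors.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_gmt <- function(sets, path) {
  writeLines(vapply(names(sets), function(nm) {
    paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t")
  }, character(1)), path)
  invisible(path)
}
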