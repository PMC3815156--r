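#' Assemble candidate genes from the three feature lists
#'
#' Harmonizes gene symbols (upper-cased) and computes the union plus all
#' seven Venn regions for the differentially expressed (DE), alternatively
#' spliced (AS) and variant-bearing (SNV) gene sets.
#'
#' @param de,as_,snv character vectors of gene symbols.
#' @return list of class \code{"feature_set"}: \code{de}, \code{as_},
#'   \code{snv}, \code{union}, and \code{venn} (named counts for
#'   de_only, as_only, snv_only, de_as, de_snv, as_snv, de_as_snv).
#' @export
assemble_candidate_genes <- function(de, as_, snv) {
  de <- unique(toupper(de)); as_ <- unique(toupper(as_))
  snv <- unique(toupper(snv))
  u <- union(union(de, as_), snv)
  if (!length(u)) stop("empty candidate union")
  in_de <- u %in% de; in_as <- u %in% as_; in_snv <- u %in% snv
  venn <- c(
    de_only  = sum(in_de & !in_as & !in_snv),
    as_only  = sum(!in_de & in_as & !in_snv),
    snv_only = sum(!in_de & !in_as & in_snv),
    de_as    = sum(in_de & in_as & !in_snv),
    de_snv   = sum(in_de & !in_as & in_snv),
    as_snv   = sum(!in_de & in_as & in_snv),
    de_as_snv = sum(in_de & in_as & in_snv))
  structure(list(de = de, as_ = as_, snv = snv, union = u, venn = venn),
            class = "feature_set")
}

#' Read an interaction edge list (TSV, two symbol columns)
#' @param path TSV path with two gene-symbol columns (no header or any
#'   header starting with "#").
#' @return data.frame \code{from}, \code{to}, upper-cased, deduplicated,
#'   self-loops dropped.
#' @export
read_edge_list <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          comment.char = "#", stringsAsFactors = FALSE)
  edges <- data.frame(from = toupper(df[[1]]), to = toupper(df[[2]]),
                      stringsAsFactors = FALSE)
  edges <- edges[edges$from != edges$to, , drop = FALSE]
  key <- ifelse(edges$from < edges$to,
                paste(edges$from, edges$to), paste(edges$to, edges$from))
  edges[!duplicated(key), , drop = FALSE]
}

#' Read a GMT gene-set file
#' @param path GMT path (name, description, members... per line).
#' @return named list of upper-cased gene vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    if (length(f) < 3) stop("GMT line with fewer than 3 fields")
    unique(toupper(f[-(1:2)]))
  })
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`,
                        character(1), 1)
  sets
}

#' Induced candidate-gene interaction network
#'
#' Builds the undirected simple subgraph on edges whose both endpoints are
#' candidate genes. Linker genes (interactors outside the candidate list)
#' are excluded, as are candidates left without any candidate-candidate
#' edge, so the model measures direct connectivity only.
#'
#' @param candidates character vector of candidate gene symbols.
#' @param edges edge data.frame (\code{from}, \code{to}) or path accepted by
#'   \code{\link{read_edge_list}}.
#' @return list of class \code{"interactome_model"}: \code{graph} (igraph),
#'   \code{n_nodes}, \code{n_edges}.
#' @export
induced_network <- function(candidates, edges) {
  if (is.character(edges) && length(edges) == 1) edges <- read_edge_list(edges)
  candidates <- unique(toupper(candidates))
  edges$from <- toupper(edges$from)
  edges$to <- toupper(edges$to)
  keep <- edges$from %in% candidates & edges$to %in% candidates
  sub <- edges[keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(sub, directed = FALSE)
  g <- igraph::simplify(g)
  structure(list(graph = g,
                 n_nodes = igraph::vcount(g),
                 n_edges = igraph::ecount(g)),
            class = "interactome_model")
}

#' Degree statistics of an interactome model
#'
#' @param model from \code{\link{induced_network}}.
#' @return list: \code{table} (gene, degree, neighborhood connectivity =
#'   mean degree of neighbors), \code{n_degree_ge5}, \code{n_degree_ge10}.
#' @export
network_stats <- function(model) {
  g <- model$graph
  if (igraph::vcount(g) == 0) {
    return(list(table = data.frame(gene = character(0), degree = integer(0),
                                   neighborhood_connectivity = numeric(0)),
                n_degree_ge5 = 0L, n_degree_ge10 = 0L))
  }
  deg <- igraph::degree(g)
  nc <- vapply(seq_along(deg), function(i) {
    nb <- igraph::neighbors(g, i)
    if (!length(nb)) return(NA_real_)
    mean(deg[nb])
  }, numeric(1))
  list(table = data.frame(gene = igraph::V(g)$name, degree = as.integer(deg),
                          neighborhood_connectivity = nc,
                          stringsAsFactors = FALSE),
       n_degree_ge5 = sum(deg >= 5), n_degree_ge10 = sum(deg >= 10))
}

#' Random-draw null for network integration
#'
#' Draws gene sets of the observed candidate-list size uniformly without
#' replacement from the universe, builds each induced network, and
#' summarizes node and edge counts (sample mean/sd, n - 1 denominator).
#' With \code{exhaustive = TRUE} all subsets are enumerated instead
#' (feasible only for tiny universes).
#'
#' @param universe character vector of genes to draw from.
#' @param draw_size number of genes per draw.
#' @param edges edge data.frame or path.
#' @param n_draws number of random draws (default 20).
#' @param seed RNG seed.
#' @param observed optional \code{interactome_model}; when given, z-scores
#'   for its node/edge counts are reported.
#' @param exhaustive enumerate all \code{choose(|universe|, draw_size)}
#'   subsets exactly.
#' @return list of class \code{"null_distribution"}: \code{draws}
#'   (data.frame nodes/edges), \code{mean_nodes}, \code{sd_nodes},
#'   \code{mean_edges}, \code{sd_edges}, and \code{z_nodes}/\code{z_edges}
#'   when \code{observed} is supplied (Inf with matching sign if sd = 0).
#' @export
random_network_null <- function(universe, draw_size, edges, n_draws = 20,
                                seed = 1, observed = NULL,
                                exhaustive = FALSE) {
  if (is.character(edges) && length(edges) == 1) edges <- read_edge_list(edges)
  universe <- unique(toupper(universe))
  if (draw_size > length(universe)) stop("draw_size exceeds universe")
  if (exhaustive) {
    subsets <- utils::combn(universe, draw_size, simplify = FALSE)
  } else {
    set.seed(seed)
    subsets <- replicate(n_draws, sample(universe, draw_size),
                         simplify = FALSE)
  }
  draws <- do.call(rbind, lapply(subsets, function(s) {
    m <- induced_network(s, edges)
    data.frame(nodes = m$n_nodes, edges = m$n_edges)
  }))
  res <- list(draws = draws,
              mean_nodes = mean(draws$nodes),
              sd_nodes = stats::sd(draws$nodes),
              mean_edges = mean(draws$edges),
              sd_edges = stats::sd(draws$edges))
  if (!is.null(observed)) {
    zval <- function(obs, m, s) {
      if (is.na(s) || s == 0) {
        if (obs == m) 0 else sign(obs - m) * Inf
      } else (obs - m) / s
    }
    res$z_nodes <- zval(observed$n_nodes, res$mean_nodes, res$sd_nodes)
    res$z_edges <- zval(observed$n_edges, res$mean_edges, res$sd_edges)
  }
  class(res) <- "null_distribution"
  res
}

#' Modularity-based module detection
#'
#' Louvain community detection at resolution 1, deterministic given the
#' seed. Module labels are arbitrary; sizes are reported.
#'
#' @param model \code{interactome_model}.
#' @param seed RNG seed.
#' @return list: \code{membership} (named integer vector gene -> module),
#'   \code{sizes}, \code{n_modules}, \code{modularity}.
#' @export
detect_modules <- function(model, seed = 1) {
  g <- model$graph
  if (igraph::vcount(g) == 0) stop("empty network model")
  set.seed(seed)
  cl <- igraph::cluster_louvain(g)
  mem <- igraph::membership(cl)
  list(membership = mem, sizes = as.integer(table(mem)),
       n_modules = length(unique(mem)),
       modularity = igraph::modularity(cl))
}

#' Exact pathway enrichment from a 2x2 contingency construction
#'
#' Given a candidate universe of \code{G} genes of which \code{N} satisfy
#' one criterion (e.g. incorporated into the network, or differentially
#' expressed in a validation cohort) and a pathway of \code{P} genes of
#' which \code{m} satisfy it, tests enrichment with the one-sided Fisher
#' exact test on the table \code{[[m, N-m], [P-m, G-N-P+m]]}, i.e. the
#' hypergeometric upper tail P(X >= m) with population G, P successes and
#' N draws.
#'
#' @param G,N,P,m contingency constants (see Details).
#' @return list: \code{p} (one-sided), \code{odds_ratio}
#'   (\code{m(G-N-P+m) / ((N-m)(P-m))}), \code{table} (2x2 matrix).
#' @export
fisher_enrichment <- function(G, N, P, m) {
  cells <- c(m = m, `N-m` = N - m, `P-m` = P - m, `G-N-P+m` = G - N - P + m)
  if (any(cells < 0)) {
    stop("negative contingency cell: ",
         paste(names(cells)[cells < 0], collapse = ", "))
  }
  p <- stats::phyper(m - 1, P, G - P, N, lower.tail = FALSE)
  or <- (m * (G - N - P + m)) / ((N - m) * (P - m))
  list(p = p, odds_ratio = or,
       table = matrix(cells, 2, 2, byrow = TRUE,
                      dimnames = list(c("in_pathway", "not_in_pathway"),
                                      c("criterion", "no_criterion"))))
}

#' Per-gene differential-expression flags for a validation cohort
#'
#' Reuses \code{\link{dtk_pairwise}} on log2(x + 1) validation counts and
#' reports, per gene and per group pair, whether p < alpha — the \code{m}
#' inputs of \code{\link{fisher_enrichment}} per pathway and comparison.
#' Genes absent from the validation counts are recorded as unflagged with a
#' warning.
#'
#' @param validation_counts gene x sample matrix.
#' @param groups group label per sample.
#' @param genes genes to test (default all rows).
#' @param alpha flag threshold (default 0.05).
#' @return data.frame: \code{gene}, one logical column
#'   \code{flag_<g1>_vs_<g2>} per pair.
#' @export
validation_de_flags <- function(validation_counts, groups, genes = NULL,
                                alpha = 0.05) {
  validation_counts <- as.matrix(validation_counts)
  groups <- as.character(groups)
  if (is.null(genes)) genes <- rownames(validation_counts)
  genes <- toupper(genes)
  rn <- toupper(rownames(validation_counts))
  absent <- setdiff(genes, rn)
  if (length(absent)) {
    warning(length(absent), " gene(s) absent from validation counts, ",
            "recorded as unflagged")
  }
  glev <- unique(groups)
  pairs <- utils::combn(glev, 2, simplify = FALSE)
  cols <- vapply(pairs, function(pr) paste0("flag_", pr[1], "_vs_", pr[2]),
                 character(1))
  out <- matrix(FALSE, length(genes), length(pairs),
                dimnames = list(genes, cols))
  lv <- log2(validation_counts + 1)
  for (g in intersect(genes, rn)) {
    x <- lv[match(g, rn), ]
    dtk <- dtk_pairwise(split(x, groups))
    for (i in seq_along(pairs)) {
      pr <- pairs[[i]]
      row <- (dtk$group1 == pr[1] & dtk$group2 == pr[2]) |
             (dtk$group1 == pr[2] & dtk$group2 == pr[1])
      out[g, i] <- dtk$p[row] < alpha
    }
  }
  data.frame(gene = genes, out, row.names = NULL, stringsAsFactors = FALSE)
}
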