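#' Generate a four-cohort gene count matrix with planted DE genes
#'
#' Negative-binomial counts per gene and sample, baseline means lognormal
#' across genes, with the planted differentially expressed genes shifted by
#' \code{de_log2fc} in the HER2 group only (half up, half down).
#' Deterministic given the config seed.
#'
#' @param config \code{\link{simulation_config}}.
#' @return list: \code{counts} (genes x samples integer matrix),
#'   \code{groups} (named sample -> group vector), \code{truth}
#'   (data.frame \code{gene}, \code{direction}).
#' @export
generate_cohort_counts <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  groups <- .cohort_groups(config$n_per_group)
  n_s <- length(groups)
  genes <- sprintf("G%05d", seq_len(config$n_genes))
  # baseline means comfortably above the detection filter for most genes
  mu <- 2^stats::rnorm(config$n_genes, mean = 7, sd = 1.5)
  # plant differential genes among depth-adequate genes: a shift in a gene
  # near the detection limit is not a recoverable signal
  adequate <- which(mu >= 64)
  if (config$n_de_genes > length(adequate)) {
    stop("not enough depth-adequate genes to plant n_de_genes")
  }
  de_idx <- if (config$n_de_genes > 0) {
    sample(adequate, config$n_de_genes)
  } else integer(0)
  direction <- rep_len(c(1, -1), length(de_idx))
  lfc <- rep(0, config$n_genes)
  lfc[de_idx] <- direction * config$de_log2fc
  her2 <- groups == "HER2"
  size <- if (config$nb_dispersion == 0) Inf else 1 / config$nb_dispersion
  counts <- matrix(0L, config$n_genes, n_s,
                   dimnames = list(genes, names(groups)))
  for (j in seq_len(n_s)) {
    mu_j <- mu * if (her2[j]) 2^lfc else 1
    counts[, j] <- if (is.finite(size)) {
      stats::rnbinom(config$n_genes, mu = mu_j, size = size)
    } else {
      stats::rpois(config$n_genes, lambda = mu_j)
    }
  }
  list(counts = counts, groups = groups,
       truth = data.frame(gene = genes[de_idx], direction = direction,
                          stringsAsFactors = FALSE))
}

#' Split gene counts into isoform counts with planted splicing switches
#'
#' Distributes each gene's counts across its isoforms with a per-gene
#' multinomial draw; isoform counts therefore sum exactly to the gene count
#' in every sample. Genes with a planted switch have their first isoform's
#' baseline proportion shifted by \code{splice_shift} in HER2 samples
#' (renormalized), so for two-isoform genes a 0.3 baseline with shift 0.4
#' becomes 0.7.
#'
#' @param cohort result of \code{\link{generate_cohort_counts}}.
#' @param config \code{\link{simulation_config}}.
#' @return list: \code{iso_counts} (transcripts x samples), \code{tx2gene},
#'   \code{truth} (data.frame \code{transcript}, \code{gene}).
#' @export
generate_isoform_counts <- function(cohort, config) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$n_isoforms_per_gene < 1) stop("n_isoforms_per_gene must be >= 1")
  set.seed(config$seed + 1L)
  counts <- cohort$counts
  groups <- cohort$groups
  genes <- rownames(counts)
  k <- config$n_isoforms_per_gene
  tx <- as.vector(t(outer(genes, seq_len(k), function(g, i) paste0(g, ".T", i))))
  tx2gene <- stats::setNames(rep(genes, each = k), tx)
  # baseline first-isoform proportion 0.3, remainder split evenly
  base_prop <- if (k == 1) 1 else c(0.3, rep(0.7 / (k - 1), k - 1))
  spliced <- if (k >= 2 && config$n_spliced_genes > 0) {
    sample(genes, min(config$n_spliced_genes, length(genes)))
  } else character(0)
  her2 <- groups == "HER2"
  iso <- matrix(0L, length(tx), ncol(counts),
                dimnames = list(tx, colnames(counts)))
  for (g in seq_along(genes)) {
    rows <- ((g - 1) * k + 1):(g * k)
    shift_prop <- base_prop
    if (genes[g] %in% spliced && k >= 2) {
      shift_prop[1] <- min(1, base_prop[1] + config$splice_shift)
      shift_prop[-1] <- (1 - shift_prop[1]) * base_prop[-1] / sum(base_prop[-1])
    }
    for (j in seq_len(ncol(counts))) {
      p <- if (her2[j]) shift_prop else base_prop
      n <- counts[g, j]
      iso[rows, j] <- if (n > 0) stats::rmultinom(1, n, p)[, 1] else 0L
    }
  }
  truth_tx <- if (length(spliced)) paste0(spliced, ".T1") else character(0)
  list(iso_counts = iso, tx2gene = tx2gene,
       truth = data.frame(transcript = truth_tx, gene = spliced,
                          stringsAsFactors = FALSE))
}
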