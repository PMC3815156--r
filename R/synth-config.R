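#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic-data generators. The
#' defaults emulate the four-cohort study design: 8 samples in each of the
#' benign, ER+, TN and HER2 groups, negative-binomial gene counts with a
#' single global dispersion, group-specific expression shifts planted in the
#' HER2 group only, multinomial isoform splits with planted HER2 splicing
#' switches, 50 nt reads, and variant classes covering clean somatic
#' variants plus the artifact classes the calling filters target.
#'
#' @param n_per_group samples per group (default 8, the study design).
#' @param n_genes number of genes in the count matrix.
#' @param n_de_genes planted differentially expressed genes.
#' @param de_log2fc log2 fold change planted in the HER2 group.
#' @param nb_dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param n_isoforms_per_gene isoforms per gene (>= 1).
#' @param splice_shift HER2 shift of the planted isoform's proportion, in
#'   [0, 1].
#' @param n_spliced_genes genes with a planted splicing switch.
#' @param n_variants planted variant sites.
#' @param variant_depth_range integer pair: total depth range at variant
#'   sites.
#' @param vaf_range variant allele fraction range, within (0, 1].
#' @param artifact_fractions named fractions for classes strand_biased,
#'   end_biased, low_depth, germline_shared; the remainder are clean somatic.
#' @param read_length read length in bases (default 50).
#' @param end_window read-end window used by the end-bias artifact class.
#' @param n_network_genes genes in the interaction graph.
#' @param community_sizes planted community sizes (sum <= n_network_genes).
#' @param p_within,p_between stochastic-block-model edge probabilities.
#' @param seed RNG seed; identical config + seed gives identical output.
#' @return validated list of class \code{"simulation_config"}.
#' @export
simulation_config <- function(n_per_group = 8,
                              n_genes = 2000,
                              n_de_genes = 50,
                              de_log2fc = 2,
                              nb_dispersion = 0.15,
                              n_isoforms_per_gene = 2,
                              splice_shift = 0.4,
                              n_spliced_genes = 20,
                              n_variants = 30,
                              variant_depth_range = c(20L, 60L),
                              vaf_range = c(0.2, 0.5),
                              artifact_fractions = c(strand_biased = 0.15,
                                                     end_biased = 0.15,
                                                     low_depth = 0.1,
                                                     germline_shared = 0.15),
                              read_length = 50,
                              end_window = 5,
                              n_network_genes = 300,
                              community_sizes = rep(30L, 5),
                              p_within = 0.5,
                              p_between = 0.02,
                              seed = 1) {
  cfg <- list(n_per_group = as.integer(n_per_group),
              n_genes = as.integer(n_genes),
              n_de_genes = as.integer(n_de_genes),
              de_log2fc = de_log2fc,
              nb_dispersion = nb_dispersion,
              n_isoforms_per_gene = as.integer(n_isoforms_per_gene),
              splice_shift = splice_shift,
              n_spliced_genes = as.integer(n_spliced_genes),
              n_variants = as.integer(n_variants),
              variant_depth_range = as.integer(variant_depth_range),
              vaf_range = vaf_range,
              artifact_fractions = artifact_fractions,
              read_length = as.integer(read_length),
              end_window = as.integer(end_window),
              n_network_genes = as.integer(n_network_genes),
              community_sizes = as.integer(community_sizes),
              p_within = p_within, p_between = p_between,
              seed = as.integer(seed))
  if (cfg$n_per_group < 2 || cfg$n_genes < 1) {
    stop("non-positive dimensions: need n_per_group >= 2 and n_genes >= 1")
  }
  if (cfg$n_de_genes > cfg$n_genes) stop("n_de_genes exceeds n_genes")
  if (cfg$nb_dispersion < 0) stop("nb_dispersion must be >= 0")
  if (cfg$n_isoforms_per_gene < 1) stop("n_isoforms_per_gene must be >= 1")
  if (cfg$splice_shift < 0 || cfg$splice_shift > 1) {
    stop("splice_shift must lie in [0, 1]")
  }
  if (any(cfg$vaf_range <= 0) || any(cfg$vaf_range > 1)) {
    stop("vaf_range must lie within (0, 1]")
  }
  need <- c("strand_biased", "end_biased", "low_depth", "germline_shared")
  if (!all(need %in% names(cfg$artifact_fractions))) {
    stop("artifact_fractions must name: ", paste(need, collapse = ", "))
  }
  af <- cfg$artifact_fractions[need]
  if (any(af < 0) || any(af > 1) || sum(af) > 1) {
    stop("artifact_fractions must lie in [0, 1] and sum to <= 1")
  }
  if (cfg$read_length < 2 * cfg$end_window) {
    stop("read_length must be >= 2 * end_window")
  }
  if (sum(cfg$community_sizes) > cfg$n_network_genes) {
    stop("community sizes sum exceeds n_network_genes")
  }
  if (cfg$p_within < 0 || cfg$p_within > 1 ||
      cfg$p_between < 0 || cfg$p_between > 1) {
    stop("edge probabilities must lie in [0, 1]")
  }
  if (cfg$p_within < cfg$p_between) {
    warning("p_within < p_between: planted modules will not be recoverable")
  }
  structure(cfg, class = "simulation_config")
}

# group labels in fixed sample order: benign, ER+, TN, HER2
.cohort_groups <- function(n_per_group) {
  groups <- rep(c("benign", "ER+", "TN", "HER2"), each = n_per_group)
  prefix <- rep(c("B", "E", "T", "H"), each = n_per_group)
  names(groups) <- paste0(prefix, rep(seq_len(n_per_group), times = 4))
  groups
}
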