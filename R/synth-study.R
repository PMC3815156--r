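#' Generate and write a complete synthetic study
#'
#' Runs every generator and writes the file formats the pipeline consumes:
#' counts.tsv, groups.tsv, isoforms.tsv, per-sample pileup pairs,
#' known_sites.vcf, genes.refflat, genome.fa, network.tsv, sets.gmt,
#' ec50.tsv, survival.tsv, and truth side-car TSVs under truth/ (the truth
#' files are never read by any pipeline stage). Identical config + seed
#' yields byte-identical files.
#'
#' @param config \code{\link{simulation_config}}.
#' @param outdir output directory.
#' @return list of all generated objects and file paths, invisibly.
#' @export
simulate_study <- function(config, outdir) {
  stopifnot(inherits(config, "simulation_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  truth_dir <- file.path(outdir, "truth")
  dir.create(truth_dir, showWarnings = FALSE)

  cohort <- generate_cohort_counts(config)
  iso <- generate_isoform_counts(cohort, config)
  pile <- generate_pileup_pair(config, outdir)
  net <- generate_network_and_sets(config)

  norm <- mode_normalize(cohort$counts)
  pheno <- generate_phenotypes(
    log2(norm$values + 1), config,
    response_genes = utils::head(cohort$truth$gene, 5),
    outcome_genes = utils::head(cohort$truth$gene, 10))

  write_tsv <- function(df, name, dir = outdir) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  counts_df <- data.frame(gene = rownames(cohort$counts), cohort$counts,
                          check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(counts_df, "counts.tsv")
  write_tsv(data.frame(sample = names(cohort$groups),
                       group = unname(cohort$groups)), "groups.tsv")
  iso_df <- data.frame(transcript = rownames(iso$iso_counts),
                       gene = unname(iso$tx2gene[rownames(iso$iso_counts)]),
                       iso$iso_counts, check.names = FALSE,
                       stringsAsFactors = FALSE)
  write_tsv(iso_df, "isoforms.tsv")
  utils::write.table(net$edges, file.path(outdir, "network.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  write_gmt(net$sets, file.path(outdir, "sets.gmt"))
  write_tsv(pheno$ec50, "ec50.tsv")
  write_tsv(pheno$survival, "survival.tsv")

  write_tsv(cohort$truth, "de_genes.tsv", truth_dir)
  write_tsv(iso$truth, "spliced_transcripts.tsv", truth_dir)
  write_tsv(pile$truth, "variants.tsv", truth_dir)
  write_tsv(data.frame(gene = names(net$truth),
                       community = unname(net$truth)),
            "communities.tsv", truth_dir)
  write_tsv(data.frame(gene = pheno$truth$outcome_genes),
            "outcome_genes.tsv", truth_dir)

  invisible(list(config = config, cohort = cohort, iso = iso, pileups = pile,
                 network = net, phenotypes = pheno, outdir = outdir))
}

#' Read a gene count TSV (gene column + one column per sample)
#' @param path counts.tsv path.
#' @return integer matrix genes x samples.
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Read an isoform count TSV (transcript, gene, then sample columns)
#' @param path isoforms.tsv path.
#' @return list: \code{iso_counts} matrix, \code{tx2gene} named vector.
#' @export
read_isoforms_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(m) <- df[[1]]
  list(iso_counts = m, tx2gene = stats::setNames(df[[2]], df[[1]]))
}

#' Read a sample -> group TSV
#' @param path groups.tsv path (columns sample, group).
#' @return named character vector.
#' @export
read_groups_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  stats::setNames(df$group, df$sample)
}
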