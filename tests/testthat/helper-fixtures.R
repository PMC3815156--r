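# shared fixtures, built once per test run and cached

.fixture_cache <- new.env(parent = emptyenv())

# small complete synthetic study (counts, isoforms, pileups, network, pheno)
small_study <- function() {
  if (is.null(.fixture_cache$study)) {
    cfg <- simulation_config(n_genes = 200, n_de_genes = 10,
                             n_spliced_genes = 8, n_variants = 20, seed = 42)
    dir <- file.path(tempdir(), "her2_fixture_study")
    .fixture_cache$study <- simulate_study(cfg, dir)
  }
  .fixture_cache$study
}

# per-sample eSNV call tables for the small study
small_study_calls <- function() {
  if (is.null(.fixture_cache$calls)) {
    st <- small_study()
    p <- st$pileups
    known <- read_known_sites(p$known_sites)
    rf <- read_refflat(p$refflat)
    gen <- read_genome(p$genome)
    calls <- lapply(seq_len(nrow(p$pileups)), function(i) {
      call_sample_esnv(p$pileups$bwa[i], p$pileups$tophat[i], rf, gen,
                       known, p$pileups$sample[i])
    })
    names(calls) <- p$pileups$sample
    .fixture_cache$calls <- calls
  }
  .fixture_cache$calls
}

# manual two-exon gene models (one per strand) with known codon content:
# CDS sense = ATG GAC CAA TGG ... TAA so consequences are hand-checkable
manual_gene_models <- function() {
  cds <- "ATGGACCAATGGTAA"            # M D Q W *
  plus_seq <- paste0("NNNNN", substr(cds, 1, 9), "GTTTTTAG",
                     substr(cds, 10, 15), "NNNNN")
  # exon1 = pos 6..14 (1-based), intron 15..22, exon2 = 23..28
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(cds, "")[[1]]),
                                     collapse = ""))
  minus_seq <- paste0("NNNNN", substr(rc, 1, 6), "GTTTTTAG",
                      substr(rc, 7, 15), "NNNNN")
  refflat <- data.frame(
    gene = c("PLUSG", "MINUSG"), transcript = c("PT1", "MT1"),
    chrom = c("chrP", "chrM"), strand = c("+", "-"),
    tx_start = c(5L, 5L), tx_end = c(28L, 28L),
    cds_start = c(5L, 5L), cds_end = c(28L, 28L),
    exon_count = c(2L, 2L), stringsAsFactors = FALSE)
  refflat$exon_starts <- list(c(5L, 22L), c(5L, 19L))
  refflat$exon_ends <- list(c(14L, 28L), c(11L, 28L))
  list(refflat = refflat,
       genome = c(chrP = plus_seq, chrM = minus_seq))
}
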