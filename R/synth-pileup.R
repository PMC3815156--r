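.BASES <- c("A", "C", "G", "T")

.revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# toy gene models: 2 exons x 150 bp on chr1, alternating strand, CDS = exons;
# sense CDS is 99 random non-stop codons plus a terminal TAA
.build_gene_models <- function(n_model_genes) {
  codons <- apply(expand.grid(.BASES, .BASES, .BASES), 1, paste, collapse = "")
  nonstop <- setdiff(codons, c("TAA", "TAG", "TGA"))
  exon_len <- 150L; intron_len <- 60L; spacer <- 100L
  chromseq <- character(0)
  cursor <- 0L
  rows <- vector("list", n_model_genes)
  for (i in seq_len(n_model_genes)) {
    strand <- if (i %% 2 == 1) "+" else "-"
    cds_sense <- paste(c(sample(nonstop, 99, replace = TRUE), "TAA"),
                       collapse = "")
    genomic_cds <- if (strand == "+") cds_sense else .revcomp(cds_sense)
    spacer_seq <- paste(sample(.BASES, spacer, replace = TRUE), collapse = "")
    intron_seq <- paste(sample(.BASES, intron_len, replace = TRUE),
                        collapse = "")
    e1 <- substr(genomic_cds, 1, exon_len)
    e2 <- substr(genomic_cds, exon_len + 1, 2 * exon_len)
    tx_start <- cursor + spacer
    ex1 <- c(tx_start, tx_start + exon_len)
    ex2 <- c(ex1[2] + intron_len, ex1[2] + intron_len + exon_len)
    chromseq <- c(chromseq, spacer_seq, e1, intron_seq, e2)
    cursor <- ex2[2]
    rows[[i]] <- data.frame(
      gene = sprintf("TGENE%02d", i), transcript = sprintf("TTX%02d", i),
      chrom = "chr1", strand = strand, tx_start = tx_start, tx_end = ex2[2],
      cds_start = tx_start, cds_end = ex2[2], exon_count = 2L,
      stringsAsFactors = FALSE)
    rows[[i]]$exon_starts <- list(c(ex1[1], ex2[1]))
    rows[[i]]$exon_ends <- list(c(ex1[2], ex2[2]))
  }
  refflat <- do.call(rbind, rows)
  genome <- c(chr1 = paste(chromseq, collapse = ""))
  list(refflat = refflat, genome = genome)
}

# pick a coding position in tx and an alt base whose consequence is
# `want` ("missense" or "synonymous"); returns genomic pos/ref/alt
.plant_coding_variant <- function(tx, genome, want = "missense") {
  cds_pos <- .cds_positions(tx)
  code <- Biostrings::GENETIC_CODE
  for (attempt in seq_len(200)) {
    codon_i <- sample(0:98, 1)                  # avoid the stop codon
    within <- sample(1:3, 1)
    idx <- codon_i * 3L + within
    gpos <- cds_pos[idx]
    bases <- vapply(cds_pos[(codon_i * 3L + 1L):(codon_i * 3L + 3L)],
                    function(p) substr(genome[[tx$chrom]], p, p), character(1))
    if (tx$strand == "-") bases <- unname(.revcomp_base(bases))
    ref_aa <- unname(code[paste(bases, collapse = "")])
    for (alt_sense in sample(setdiff(.BASES, bases[within]))) {
      nb <- bases; nb[within] <- alt_sense
      alt_aa <- unname(code[paste(nb, collapse = "")])
      csq <- if (alt_aa == ref_aa) "synonymous"
             else if (alt_aa == "*") "stopgain"
             else if (ref_aa == "*") "stoploss"
             else "missense"
      if (csq == want) {
        ref_g <- substr(genome[[tx$chrom]], gpos, gpos)
        alt_g <- if (tx$strand == "-") unname(.revcomp_base(alt_sense))
                 else alt_sense
        return(list(chrom = tx$chrom, pos = gpos, ref = ref_g, alt = alt_g,
                    gene = tx$gene, consequence = want))
      }
    }
  }
  stop("could not plant a ", want, " variant")
}

# one pileup line; offsets are distances from the nearer read end
.pileup_line <- function(chrom, pos, ref, alt = NULL, ref_depth,
                         alt_depth = 0, alt_strands = NULL,
                         alt_offsets = NULL, read_length = 50) {
  L <- read_length
  ref_strands <- rep_len(c("+", "-"), ref_depth)
  ref_p <- sample(0:(L - 1), ref_depth, replace = TRUE)
  ref_off <- pmin(ref_p, L - 1 - ref_p)
  syms <- ifelse(ref_strands == "+", ".", ",")
  offs <- ref_off
  if (alt_depth > 0) {
    alt_syms <- ifelse(alt_strands == "+", alt, tolower(alt))
    syms <- c(syms, alt_syms)
    offs <- c(offs, alt_offsets)
  }
  ord <- sample(length(syms))
  syms <- syms[ord]; offs <- offs[ord]
  syms[1] <- paste0("^~", syms[1])
  syms[length(syms)] <- paste0(syms[length(syms)], "$")
  depth <- ref_depth + alt_depth
  paste(chrom, pos, ref, depth, paste(syms, collapse = ""),
        paste(rep("I", depth), collapse = ""),
        paste(offs, collapse = ","), sep = "\t")
}

#' Generate paired per-sample pileups with planted variants and artifacts
#'
#' Builds a toy genome and two-exon gene models, plants \code{n_variants}
#' coding variants partitioned into classes (clean somatic, strand-biased,
#' read-end-biased, low-depth, shared germline), and writes one pileup file
#' per sample per aligner dialect plus a known-sites VCF, the refFlat gene
#' model and the genome FASTA. Clean somatic variants are planted in 1-2
#' HER2 samples with balanced read strands and at least one alternate read
#' away from the read ends, so only a defective filter could remove them.
#' Strand-biased sites carry all alternate reads on one strand; end-biased
#' sites carry all alternate reads within \code{end_window} bases of a read
#' end; low-depth sites have total depth 3; germline sites appear in every
#' group and in the known-sites file. Each pileup line carries a 7th column
#' with per-read offsets from the nearer read end.
#'
#' @param config \code{\link{simulation_config}}.
#' @param outdir output directory (created if missing).
#' @return list: \code{pileups} (data.frame sample, bwa, tophat paths),
#'   \code{known_sites}, \code{refflat}, \code{genome} (paths),
#'   \code{groups}, \code{truth} (data.frame chrom, pos, ref, alt, class,
#'   gene, consequence, carriers).
#' @export
generate_pileup_pair <- function(config, outdir) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$read_length < 2 * config$end_window) {
    stop("read_length must be >= 2 * end_window")
  }
  set.seed(config$seed + 2L)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  groups <- .cohort_groups(config$n_per_group)
  samples <- names(groups)
  models <- .build_gene_models(max(6L, ceiling(config$n_variants / 4)))
  genome <- models$genome
  refflat <- models$refflat

  nv <- config$n_variants
  af <- config$artifact_fractions
  n_cls <- c(strand_biased = round(af[["strand_biased"]] * nv),
             end_biased = round(af[["end_biased"]] * nv),
             low_depth = round(af[["low_depth"]] * nv),
             germline_shared = round(af[["germline_shared"]] * nv))
  n_true <- nv - sum(n_cls)
  classes <- c(rep("true_somatic", n_true),
               rep(names(n_cls), times = n_cls))

  her2 <- samples[groups == "HER2"]
  used_pos <- integer(0)
  truth <- vector("list", nv)
  carriers <- vector("list", nv)
  for (v in seq_len(nv)) {
    repeat {
      tx <- refflat[sample(nrow(refflat), 1), ]
      pv <- .plant_coding_variant(tx, genome, "missense")
      if (!pv$pos %in% used_pos) break
    }
    used_pos <- c(used_pos, pv$pos)
    cls <- classes[v]
    car <- switch(cls,
      true_somatic = sample(her2, sample(1:2, 1)),
      strand_biased = sample(her2, 1),
      end_biased = sample(her2, 1),
      low_depth = sample(her2, 1),
      germline_shared = as.character(vapply(split(samples, groups[samples]),
                                            sample, character(1), size = 1)))
    carriers[[v]] <- car
    truth[[v]] <- data.frame(chrom = pv$chrom, pos = pv$pos, ref = pv$ref,
                             alt = pv$alt, class = cls, gene = pv$gene,
                             consequence = pv$consequence,
                             carriers = paste(sort(car), collapse = ","),
                             stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)

  L <- config$read_length; E <- config$end_window
  draw_site <- function(cls) {
    depth <- sample(config$variant_depth_range[1]:config$variant_depth_range[2], 1)
    vaf <- stats::runif(1, config$vaf_range[1], config$vaf_range[2])
    alt_d <- max(4L, round(vaf * depth))
    if (cls == "low_depth") { depth <- 3L; alt_d <- 2L }
    strands <- switch(cls,
      strand_biased = rep("+", alt_d),
      rep_len(c("+", "-"), alt_d))
    if (cls == "end_biased") {
      p <- sample(c(0:(E - 1), (L - E):(L - 1)), alt_d, replace = TRUE)
      offs <- pmin(p, L - 1 - p)
    } else {
      p <- sample(0:(L - 1), alt_d, replace = TRUE)
      offs <- pmin(p, L - 1 - p)
      if (all(offs < E)) offs[1] <- sample(E:floor((L - 1) / 2), 1)
    }
    list(ref_depth = max(depth - alt_d, 0L), alt_depth = alt_d,
         strands = strands, offsets = offs)
  }

  pile_dir <- outdir
  paths <- data.frame(sample = samples,
                      bwa = file.path(pile_dir, paste0(samples, ".bwa.pileup")),
                      tophat = file.path(pile_dir,
                                         paste0(samples, ".tophat.pileup")),
                      stringsAsFactors = FALSE)
  for (s in seq_along(samples)) {
    lines_bwa <- character(0); lines_th <- character(0)
    ord <- order(truth$pos)
    for (v in ord) {
      is_carrier <- samples[s] %in% carriers[[v]]
      for (dialect in c("bwa", "th")) {
        if (is_carrier) {
          site <- draw_site(truth$class[v])
          ln <- .pileup_line(truth$chrom[v], truth$pos[v], truth$ref[v],
                             truth$alt[v], site$ref_depth, site$alt_depth,
                             site$strands, site$offsets, L)
        } else {
          depth <- sample(config$variant_depth_range[1]:
                          config$variant_depth_range[2], 1)
          ln <- .pileup_line(truth$chrom[v], truth$pos[v], truth$ref[v],
                             ref_depth = depth, read_length = L)
        }
        if (dialect == "bwa") lines_bwa <- c(lines_bwa, ln)
        else lines_th <- c(lines_th, ln)
      }
    }
    writeLines(lines_bwa, paths$bwa[s])
    writeLines(lines_th, paths$tophat[s])
  }

  # known sites: the germline class plus decoy positions
  known <- truth[truth$class == "germline_shared",
                 c("chrom", "pos", "ref", "alt")]
  n_decoy <- 3L
  for (d in seq_len(n_decoy)) {
    repeat {
      pos <- sample(nchar(genome[["chr1"]]), 1)
      if (!pos %in% used_pos) break
    }
    ref <- substr(genome[["chr1"]], pos, pos)
    known <- rbind(known, data.frame(chrom = "chr1", pos = pos, ref = ref,
                                     alt = sample(setdiff(.BASES, ref), 1),
                                     stringsAsFactors = FALSE))
  }
  known <- known[order(known$pos), ]
  known_path <- file.path(outdir, "known_sites.vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.",
                       known$chrom, known$pos, known$ref, known$alt)),
             known_path)

  refflat_path <- file.path(outdir, "genes.refflat")
  writeLines(vapply(seq_len(nrow(refflat)), function(i) {
    r <- refflat[i, ]
    paste(r$gene, r$transcript, r$chrom, r$strand, r$tx_start, r$tx_end,
          r$cds_start, r$cds_end, r$exon_count,
          paste0(paste(r$exon_starts[[1]], collapse = ","), ","),
          paste0(paste(r$exon_ends[[1]], collapse = ","), ","), sep = "\t")
  }, character(1)), refflat_path)

  genome_path <- file.path(outdir, "genome.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), genome_path)

  list(pileups = paths, known_sites = known_path, refflat = refflat_path,
       genome = genome_path, groups = groups, truth = truth)
}
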