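#' Read a refFlat gene model
#'
#' refFlat is tab-delimited: gene symbol, transcript id, chrom, strand,
#' txStart, txEnd, cdsStart, cdsEnd, exonCount, exonStarts, exonEnds, with
#' 0-based half-open exon and CDS bounds.
#'
#' @param path path to the refFlat file.
#' @return data.frame with list-columns \code{exon_starts}, \code{exon_ends}.
#' @export
read_refflat <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("gene", "transcript", "chrom",
                                        "strand", "tx_start", "tx_end",
                                        "cds_start", "cds_end", "exon_count",
                                        "exon_starts", "exon_ends"))
  df$exon_starts <- lapply(strsplit(df$exon_starts, ","), as.integer)
  df$exon_ends <- lapply(strsplit(df$exon_ends, ","), as.integer)
  df
}

#' Load a genome FASTA
#'
#' @param path FASTA path.
#' @return named character vector of chromosome sequences.
#' @export
read_genome <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- as.character(seqs)
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

# CDS genomic positions (1-based, in transcription order) for one transcript
.cds_positions <- function(tx) {
  pos <- integer(0)
  for (e in seq_along(tx$exon_starts[[1]])) {
    s <- max(tx$exon_starts[[1]][e], tx$cds_start)
    e_ <- min(tx$exon_ends[[1]][e], tx$cds_end)
    if (s < e_) pos <- c(pos, (s + 1L):e_)   # 0-based half-open -> 1-based
  }
  if (tx$strand == "-") rev(pos) else pos
}

.revcomp_base <- function(b) c(A = "T", C = "G", G = "C", T = "A")[b]

#' Annotate a variant's coding consequence
#'
#' Locates the codon containing a substitution through the gene model,
#' accounting for transcript strand (minus-strand transcripts are
#' reverse-complemented), and classifies it as synonymous, missense,
#' stopgain, stoploss, or non-exonic (outside every transcript's CDS).
#' Transcripts whose CDS length is not a multiple of 3 are skipped with a
#' warning. When several transcripts cover the site, the first non-synonymous
#' consequence wins (stopgain > stoploss > missense > synonymous).
#'
#' @param chrom,pos,ref,alt variant (pos 1-based; ref/alt single bases on the
#'   + genomic strand).
#' @param refflat gene model from \code{\link{read_refflat}}.
#' @param genome named chromosome sequences from \code{\link{read_genome}}.
#' @return list: \code{consequence}, \code{gene}, \code{aa_change}
#'   (e.g. "D69H", NA for non-exonic).
#' @export
annotate_variant <- function(chrom, pos, ref, alt, refflat, genome) {
  hits <- refflat[refflat$chrom == chrom &
                  refflat$tx_start < pos & pos <= refflat$tx_end, ,
                  drop = FALSE]
  best <- list(consequence = "non-exonic", gene = NA_character_,
               aa_change = NA_character_)
  rank <- c("non-exonic" = 0, synonymous = 1, missense = 2,
            stoploss = 3, stopgain = 4)
  for (r in seq_len(nrow(hits))) {
    tx <- hits[r, ]
    cds_pos <- .cds_positions(tx)
    if (!length(cds_pos)) next
    if (length(cds_pos) %% 3 != 0) {
      warning("transcript ", tx$transcript,
              " CDS length not divisible by 3; skipped")
      next
    }
    idx <- match(pos, cds_pos)
    if (is.na(idx)) next
    chromseq <- genome[[chrom]]
    codon_i <- (idx - 1L) %/% 3L
    codon_pos <- cds_pos[(codon_i * 3L + 1L):(codon_i * 3L + 3L)]
    bases <- vapply(codon_pos, function(p) substr(chromseq, p, p), character(1))
    within <- idx - codon_i * 3L
    if (tx$strand == "-") bases <- unname(.revcomp_base(bases))
    ref_tx <- if (tx$strand == "-") unname(.revcomp_base(ref)) else ref
    alt_tx <- if (tx$strand == "-") unname(.revcomp_base(alt)) else alt
    if (bases[within] != ref_tx) {
      warning("reference mismatch at ", chrom, ":", pos, " for ",
              tx$transcript, "; skipped")
      next
    }
    ref_codon <- paste(bases, collapse = "")
    alt_bases <- bases; alt_bases[within] <- alt_tx
    alt_codon <- paste(alt_bases, collapse = "")
    code <- Biostrings::GENETIC_CODE
    ref_aa <- unname(code[ref_codon]); alt_aa <- unname(code[alt_codon])
    csq <- if (ref_aa == alt_aa) "synonymous"
           else if (alt_aa == "*") "stopgain"
           else if (ref_aa == "*") "stoploss"
           else "missense"
    if (rank[csq] > rank[best$consequence]) {
      best <- list(consequence = csq, gene = tx$gene,
                   aa_change = paste0(ref_aa, codon_i + 1L, alt_aa))
    }
  }
  best
}
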