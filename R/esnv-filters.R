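#' Depth and allele-ratio candidate filter
#'
#' Classifies a summarized site: \code{"reject"} when total depth < 4, the
#' alternate-allele ratio < 0.1, or fewer than 2 alternate reads;
#' \code{"high"} when the alternate allele has >= 4 supporting reads;
#' \code{"low"} for 2-3 alternate reads (retained only for recurrence
#' reporting, never emitted as a confident call).
#'
#' @param sites site-summary data.frame from \code{\link{summarize_alleles}}.
#' @param min_depth minimum total depth (default 4).
#' @param min_ratio minimum alternate-allele ratio (default 0.1).
#' @param high_alt minimum alternate reads for high confidence (default 4).
#' @return \code{sites} with an added \code{confidence} column
#'   ("high"/"low"/"reject").
#' @export
candidate_filter <- function(sites, min_depth = 4, min_ratio = 0.1,
                             high_alt = 4) {
  conf <- rep("reject", nrow(sites))
  ok <- sites$total_depth >= min_depth & sites$alt_ratio >= min_ratio
  conf[ok & sites$alt_depth >= high_alt] <- "high"
  conf[ok & sites$alt_depth >= 2 & sites$alt_depth < high_alt] <- "low"
  sites$confidence <- conf
  sites
}

#' Strand-bias filter
#'
#' A site passes when the alternate allele is seen on both strands and the
#' minor-to-major strand count ratio exceeds \code{min_strand_ratio}. The
#' stranded counts come from the second aligner's pileup, so a variant must
#' show balanced strand support in independent alignments.
#'
#' @param alt_fwd,alt_rev alternate-allele read counts on the +/- strand.
#' @param min_strand_ratio threshold on min/max (default 0.1, strict).
#' @return logical vector: TRUE = pass.
#' @export
strand_bias_filter <- function(alt_fwd, alt_rev, min_strand_ratio = 0.1) {
  lo <- pmin(alt_fwd, alt_rev)
  hi <- pmax(alt_fwd, alt_rev)
  alt_fwd >= 1 & alt_rev >= 1 & lo / hi > min_strand_ratio
}

#' Consensus of two aligners' candidate sites
#'
#' Keeps the sites called with the same alternate allele at the same position
#' by both aligners. A site present in only one source, or with discordant
#' alternate alleles, is dropped.
#'
#' @param sites1,sites2 site-summary data.frames (e.g. BWA- and
#'   TopHat-derived) containing \code{chrom}, \code{pos}, \code{alt}.
#' @return the rows of \code{sites1} whose (chrom, pos, alt) key also occurs
#'   in \code{sites2}.
#' @export
consensus_calls <- function(sites1, sites2) {
  k1 <- paste(sites1$chrom, sites1$pos, sites1$alt, sep = ":")
  k2 <- paste(sites2$chrom, sites2$pos, sites2$alt, sep = ":")
  sites1[k1 %in% k2, , drop = FALSE]
}

#' Remove known or germline sites
#'
#' Drops variants matching a known-sites list. Matching is allele-aware by
#' default: a variant at a known position with a different alternate allele
#' is kept. Position-only matching (the convention of annotation databases
#' that store sites, not alleles) is available via \code{by_allele = FALSE}.
#'
#' @param variants data.frame with \code{chrom}, \code{pos}, \code{alt}.
#' @param known data.frame with \code{chrom}, \code{pos} and (for
#'   allele-aware matching) \code{alt}.
#' @param by_allele match on (chrom, pos, alt) (default) or (chrom, pos).
#' @return the novel subset of \code{variants}.
#' @export
filter_known <- function(variants, known, by_allele = TRUE) {
  if (!nrow(known)) return(variants)
  if (by_allele) {
    kv <- paste(variants$chrom, variants$pos, variants$alt, sep = ":")
    kk <- paste(known$chrom, known$pos, known$alt, sep = ":")
  } else {
    kv <- paste(variants$chrom, variants$pos, sep = ":")
    kk <- paste(known$chrom, known$pos, sep = ":")
  }
  variants[!(kv %in% kk), , drop = FALSE]
}

#' Read-end bias filter
#'
#' Fails a variant when every alternate-allele observation lies within
#' \code{end_window} bases of the nearer read end — the signature of
#' alignment artifacts at read termini. Variants whose alternate
#' observations have unknown offsets pass (with no offset evidence the
#' filter cannot act) and are flagged.
#'
#' @param alt_offsets integer vector of read offsets (distance from nearer
#'   read end, 0-based) for the alternate-allele observations at one site;
#'   NA = unknown.
#' @param end_window window size E in bases (default 5).
#' @return list with \code{pass} (logical) and \code{offset_unknown}
#'   (TRUE when all offsets were NA).
#' @export
end_bias_filter <- function(alt_offsets, end_window = 5) {
  known <- alt_offsets[!is.na(alt_offsets)]
  if (!length(known)) return(list(pass = TRUE, offset_unknown = TRUE))
  list(pass = any(known >= end_window), offset_unknown = FALSE)
}
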