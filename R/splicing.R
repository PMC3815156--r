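#' Per-isoform relative abundance ratios
#'
#' For each eligible gene, computes the fraction of the gene's isoform-total
#' contributed by every transcript in every sample. A gene is eligible when
#' it is expressed (its within-group median gene count exceeds the
#' expression-filter threshold in at least one group, the same rule as
#' \code{\link{filter_low_expression}}) and has at least two annotated
#' isoforms. Samples where the gene's isoform total is zero get missing
#' ratios.
#'
#' @param iso_counts matrix, transcripts x samples (non-negative; may be
#'   fractional when estimated upstream).
#' @param tx2gene named character vector mapping transcript id -> gene id.
#' @param gene_counts gene x sample count matrix used for the expression gate.
#' @param groups group label per sample.
#' @param threshold expression-gate threshold (default 16).
#' @return list with \code{ratios} (transcripts x samples, in [0,1] or NA),
#'   \code{tx2gene} restricted to eligible transcripts, and
#'   \code{eligible_genes}.
#' @export
isoform_ratios <- function(iso_counts, tx2gene, gene_counts, groups,
                           threshold = 16) {
  iso_counts <- as.matrix(iso_counts)
  missing_map <- setdiff(rownames(iso_counts), names(tx2gene))
  if (length(missing_map)) {
    stop("transcript(s) with unknown gene: ",
         paste(utils::head(missing_map, 5), collapse = ", "))
  }
  tx2gene <- tx2gene[rownames(iso_counts)]
  unknown <- setdiff(unique(tx2gene), rownames(gene_counts))
  if (length(unknown)) {
    stop("transcript mapped to gene absent from counts: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  expressed <- rownames(filter_low_expression(gene_counts, groups, threshold))
  n_iso <- table(tx2gene)
  eligible_genes <- intersect(expressed, names(n_iso)[n_iso >= 2])
  keep <- tx2gene %in% eligible_genes
  iso <- iso_counts[keep, , drop = FALSE]
  map <- tx2gene[keep]
  ratios <- iso
  for (g in eligible_genes) {
    rows <- which(map == g)
    tot <- colSums(iso[rows, , drop = FALSE])
    r <- sweep(iso[rows, , drop = FALSE], 2, tot, "/")
    r[, tot <= 0] <- NA_real_
    ratios[rows, ] <- r
  }
  list(ratios = ratios, tx2gene = map, eligible_genes = eligible_genes)
}

#' Call transcripts with group-specific splicing
#'
#' Applies \code{\link{dtk_pairwise}} to each transcript's relative-abundance
#' ratios and flags transcripts whose target-group mean ratio differs from
#' every other group at \code{p < alpha}. Missing ratios are dropped per
#' transcript (the unequal sample sizes this creates are what the
#' Welch-type comparison handles); transcripts left with fewer than two
#' non-missing ratios in any group are skipped and recorded.
#'
#' @param ratio_table result of \code{\link{isoform_ratios}}.
#' @param groups group label per sample.
#' @param target_group group tested for specificity (default "HER2").
#' @param alpha significance threshold.
#' @return list with \code{calls} (transcript-level data.frame as in
#'   \code{\link{call_group_specific}}, plus \code{gene}), \code{as_genes}
#'   (genes of flagged transcripts) and \code{skipped} (transcript ids with
#'   insufficient data).
#' @export
call_group_specific_splicing <- function(ratio_table, groups,
                                         target_group = "HER2", alpha = 0.05) {
  ratios <- ratio_table$ratios
  groups <- as.character(groups)
  stopifnot(length(groups) == ncol(ratios))
  usable <- apply(ratios, 1, function(r) {
    all(tapply(!is.na(r), groups, sum) >= 2)
  })
  skipped <- rownames(ratios)[!usable]
  if (!any(usable)) {
    return(list(calls = NULL, as_genes = character(0), skipped = skipped))
  }
  others <- setdiff(unique(groups), target_group)
  calls <- lapply(rownames(ratios)[usable], function(tx) {
    r <- ratios[tx, ]
    ok <- !is.na(r)
    dtk <- dtk_pairwise(split(r[ok], groups[ok]))
    ptarget <- vapply(others, function(o) {
      row <- (dtk$group1 == target_group & dtk$group2 == o) |
             (dtk$group2 == target_group & dtk$group1 == o)
      dtk$p[row]
    }, numeric(1))
    dir <- sign(mean(r[ok][groups[ok] == target_group]) -
                mean(r[ok][groups[ok] != target_group]))
    data.frame(transcript = tx, gene = unname(ratio_table$tx2gene[tx]),
               t(ptarget), p_max = max(ptarget), direction = dir,
               stringsAsFactors = FALSE, check.names = FALSE)
  })
  calls <- do.call(rbind, calls)
  names(calls)[3:(2 + length(others))] <- paste0("p_", others)
  calls$is_AS <- calls$p_max < alpha
  list(calls = calls,
       as_genes = unique(calls$gene[calls$is_AS]),
       skipped = skipped)
}
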