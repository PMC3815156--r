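#' Run the consensus eSNV chain on one sample
#'
#' Full dual-aligner expressed-variant workflow: summarize both pileups,
#' apply the depth/allele-ratio candidate filter to each, require strand
#' balance in the second aligner's stranded counts, keep only sites called
#' with the same alternate allele by both aligners, annotate coding
#' consequence through the gene model, drop known/germline sites, and drop
#' sites whose alternate reads sit exclusively at read ends. All filters are
#' conjunctive predicates: each is recorded per site so the final call set
#' does not depend on application order and every rejection is attributable
#' to the filter(s) that caused it.
#'
#' @param bwa_pileup,tophat_pileup pileup file paths for the two aligners.
#' @param refflat gene model (\code{\link{read_refflat}}).
#' @param genome chromosome sequences (\code{\link{read_genome}}).
#' @param known known-sites data.frame (\code{chrom}, \code{pos},
#'   \code{alt}); see \code{\link{read_known_sites}}.
#' @param sample sample identifier recorded on every call.
#' @param end_window read-end bias window in bases (default 5).
#' @param min_depth,min_ratio,high_alt candidate-filter thresholds.
#' @param known_by_allele allele-aware known-site matching (default TRUE).
#' @return data.frame, one row per alternate-evidence site from the first
#'   aligner, with site summary columns, \code{confidence},
#'   \code{consequence}, \code{gene}, \code{aa_change}, per-filter logical
#'   columns (\code{pass_candidate}, \code{pass_strand},
#'   \code{pass_consensus}, \code{pass_annotation}, \code{pass_known},
#'   \code{pass_end}), \code{pass_site_filters} (all non-confidence filters)
#'   and \code{pass} (emitted high-confidence call).
#' @export
call_sample_esnv <- function(bwa_pileup, tophat_pileup, refflat, genome,
                             known, sample, end_window = 5,
                             min_depth = 4, min_ratio = 0.1, high_alt = 4,
                             known_by_allele = TRUE) {
  obs_bwa <- parse_mpileup(bwa_pileup)
  obs_th  <- parse_mpileup(tophat_pileup)
  sites <- candidate_filter(summarize_alleles(obs_bwa),
                            min_depth = min_depth, min_ratio = min_ratio,
                            high_alt = high_alt)
  if (!nrow(sites)) {
    sites$sample <- character(0)
    return(sites)
  }
  th <- candidate_filter(summarize_alleles(obs_th),
                         min_depth = min_depth, min_ratio = min_ratio,
                         high_alt = high_alt)
  th_ok <- th[th$confidence != "reject", , drop = FALSE]

  key <- paste(sites$chrom, sites$pos, sites$alt, sep = ":")
  sites$pass_candidate <- sites$confidence != "reject"

  # consensus: same (chrom,pos,alt) candidate in the second aligner
  key_th <- paste(th_ok$chrom, th_ok$pos, th_ok$alt, sep = ":")
  sites$pass_consensus <- key %in% key_th

  # strand balance taken from the second aligner's stranded counts
  idx <- match(key, key_th)
  sites$pass_strand <- !is.na(idx) &
    strand_bias_filter(th_ok$alt_fwd[idx], th_ok$alt_rev[idx])
  sites$pass_strand[is.na(idx)] <- FALSE

  ann <- lapply(seq_len(nrow(sites)), function(i) {
    annotate_variant(sites$chrom[i], sites$pos[i], sites$ref[i],
                     sites$alt[i], refflat, genome)
  })
  sites$consequence <- vapply(ann, `[[`, character(1), "consequence")
  sites$gene <- vapply(ann, `[[`, character(1), "gene")
  sites$aa_change <- vapply(ann, `[[`, character(1), "aa_change")
  sites$pass_annotation <-
    sites$consequence %in% c("missense", "stopgain", "stoploss")

  novel <- filter_known(sites, known, by_allele = known_by_allele)
  sites$pass_known <- key %in% paste(novel$chrom, novel$pos, novel$alt,
                                     sep = ":")

  ends <- lapply(seq_len(nrow(sites)), function(i) {
    sel <- obs_bwa$chrom == sites$chrom[i] & obs_bwa$pos == sites$pos[i] &
           obs_bwa$base == sites$alt[i]
    end_bias_filter(obs_bwa$read_offset[sel], end_window = end_window)
  })
  sites$pass_end <- vapply(ends, `[[`, logical(1), "pass")
  sites$end_offset_unknown <- vapply(ends, `[[`, logical(1), "offset_unknown")

  sites$pass_site_filters <- sites$pass_candidate & sites$pass_consensus &
    sites$pass_strand & sites$pass_annotation & sites$pass_known &
    sites$pass_end
  sites$pass <- sites$pass_site_filters & sites$confidence == "high"
  sites$sample <- sample
  sites
}

#' Read a known-sites list (VCF or TSV)
#'
#' Accepts a minimal VCF (CHROM POS ID REF ALT ...) or a 3+ column TSV
#' (chrom, pos, alt). Rows are sorted by position internally.
#'
#' @param path file path.
#' @return data.frame with \code{chrom}, \code{pos}, \code{ref} (NA for
#'   TSV without ref), \code{alt}.
#' @export
read_known_sites <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      stringsAsFactors = FALSE))
  }
  f <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  if (ncol(f) >= 5) {                       # VCF-shaped
    out <- data.frame(chrom = f[, 1], pos = as.integer(f[, 2]),
                      ref = f[, 4], alt = f[, 5], stringsAsFactors = FALSE)
  } else {
    out <- data.frame(chrom = f[, 1], pos = as.integer(f[, 2]),
                      ref = NA_character_, alt = f[, 3],
                      stringsAsFactors = FALSE)
  }
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Assemble a cohort variant database
#'
#' Stacks per-sample call tables and attaches group labels, yielding a
#' queryable table with one record per variant per sample.
#'
#' @param call_list named list of per-sample call data.frames from
#'   \code{\link{call_sample_esnv}} (names = sample ids).
#' @param groups named vector mapping sample id -> group.
#' @return data.frame of all records with a \code{group} column.
#' @export
build_cohort_db <- function(call_list, groups) {
  db <- do.call(rbind, unname(call_list))
  missing <- setdiff(unique(db$sample), names(groups))
  if (length(missing)) stop("sample(s) without group: ",
                            paste(missing, collapse = ", "))
  db$group <- unname(groups[db$sample])
  rownames(db) <- NULL
  db
}

#' Variants exclusive to one cohort
#'
#' Keeps variants with at least one emitted (all filters passed,
#' high-confidence) call in the target group's samples and no emitted call
#' in any other group's samples. Support count is the number of target-group
#' samples carrying the call.
#'
#' @param db cohort database from \code{\link{build_cohort_db}}.
#' @param target_group cohort of interest (e.g. "HER2").
#' @return data.frame, one row per exclusive variant: \code{chrom},
#'   \code{pos}, \code{ref}, \code{alt}, \code{gene}, \code{consequence},
#'   \code{n_support}, \code{samples} (comma-joined ids).
#' @export
cohort_exclusive <- function(db, target_group) {
  calls <- db[db$pass, , drop = FALSE]
  if (!nrow(calls)) return(calls[, c("chrom", "pos", "ref", "alt")])
  key <- paste(calls$chrom, calls$pos, calls$alt, sep = ":")
  in_target <- calls$group == target_group
  veto <- unique(key[!in_target])
  keep_keys <- setdiff(unique(key[in_target]), veto)
  rows <- lapply(keep_keys, function(k) {
    sel <- calls[key == k & in_target, , drop = FALSE]
    data.frame(chrom = sel$chrom[1], pos = sel$pos[1], ref = sel$ref[1],
               alt = sel$alt[1], gene = sel$gene[1],
               consequence = sel$consequence[1],
               n_support = nrow(sel),
               samples = paste(sort(sel$sample), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Recurrence report across the cohort
#'
#' For every variant passing the site filters, counts samples supporting it
#' at high confidence (>= \code{high_threshold} alternate reads) and at low
#' confidence (\code{low_threshold} to \code{high_threshold - 1} alternate
#' reads). A variant is recurrent when it has high-confidence support in two
#' samples, or high-confidence support in one plus low-confidence support in
#' another.
#'
#' @param db cohort database.
#' @param high_threshold,low_threshold alternate-read thresholds (4 and 2).
#' @return data.frame: \code{chrom}, \code{pos}, \code{ref}, \code{alt},
#'   \code{gene}, \code{n_high}, \code{n_low}, \code{alt_depths}
#'   (comma-joined per-sample "sample=depth"), \code{recurrent}.
#' @export
recurrence_report <- function(db, high_threshold = 4, low_threshold = 2) {
  calls <- db[db$pass_site_filters & db$alt_depth >= low_threshold, ,
              drop = FALSE]
  if (!nrow(calls)) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      gene = character(0), n_high = integer(0),
                      n_low = integer(0), alt_depths = character(0),
                      recurrent = logical(0), stringsAsFactors = FALSE))
  }
  key <- paste(calls$chrom, calls$pos, calls$alt, sep = ":")
  rows <- lapply(split(seq_len(nrow(calls)), key), function(idx) {
    v <- calls[idx, ]
    n_high <- sum(v$alt_depth >= high_threshold)
    n_low  <- sum(v$alt_depth < high_threshold)
    data.frame(chrom = v$chrom[1], pos = v$pos[1], ref = v$ref[1],
               alt = v$alt[1], gene = v$gene[1],
               n_high = n_high, n_low = n_low,
               alt_depths = paste(paste0(v$sample, "=", v$alt_depth),
                                  collapse = ","),
               recurrent = n_high >= 2 || (n_high >= 1 && n_low >= 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}
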