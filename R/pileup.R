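#' Parse a samtools-mpileup text file into allele observations
#'
#' Reads the classic 6-column mpileup dialect (chrom, 1-based pos, ref base,
#' depth, read bases, base qualities). In the read-base string '.'/',' are
#' reference matches on the +/- strand, 'ACGTN'/'acgtn' are mismatches on the
#' +/- strand, '^X' marks a read start (the following character is a mapping
#' quality and is skipped), '$' marks a read end, '*' is a deletion
#' placeholder (kept as a symbol, no allele observation) and '+n<seq>'/
#' '-n<seq>' indel fields are skipped. An optional 7th column may carry
#' comma-separated read offsets (distance of the base from the nearer read
#' end, 0-based), one per base symbol; absent offsets are returned as NA.
#'
#' @param path path to the pileup file.
#' @return data.frame of observations: \code{chrom}, \code{pos}, \code{ref},
#'   \code{base} (observed allele), \code{strand} ("+"/"-"),
#'   \code{read_offset} (integer or NA).
#' @export
parse_mpileup <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 6) stop("malformed pileup line ", i, ": expected >= 6 fields")
    depth <- suppressWarnings(as.integer(f[4]))
    if (is.na(depth)) stop("malformed pileup line ", i, ": bad depth field")
    if (depth == 0) next
    parsed <- .parse_base_string(f[5], toupper(f[3]))
    if (length(parsed$base) != depth) {
      stop("malformed pileup line ", i, ": depth ", depth,
           " != ", length(parsed$base), " base symbols")
    }
    offs <- rep(NA_integer_, depth)
    if (length(f) >= 7 && nzchar(f[7]) && f[7] != ".") {
      o <- suppressWarnings(as.integer(strsplit(f[7], ",", fixed = TRUE)[[1]]))
      if (length(o) != depth) {
        stop("malformed pileup line ", i, ": offset column length mismatch")
      }
      offs <- o
    }
    keep <- parsed$base != "*"
    if (!any(keep)) next
    out[[i]] <- data.frame(
      chrom = f[1], pos = as.integer(f[2]), ref = toupper(f[3]),
      base = parsed$base[keep], strand = parsed$strand[keep],
      read_offset = offs[keep], stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), base = character(0),
                      strand = character(0), read_offset = integer(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# decode one read-base string; returns base/strand per retained symbol,
# '*' retained as base "*" so the depth check still balances
.parse_base_string <- function(s, ref) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  base <- character(0); strand <- character(0)
  i <- 1L; n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "^") {
      i <- i + 2L                     # skip mapq char
    } else if (ch == "$") {
      i <- i + 1L
    } else if (ch == "+" || ch == "-") {
      j <- i + 1L
      while (j <= n && grepl("[0-9]", chars[j])) j <- j + 1L
      len <- as.integer(paste(chars[(i + 1L):(j - 1L)], collapse = ""))
      i <- j + len                    # skip inserted/deleted sequence
    } else if (ch == ".") {
      base <- c(base, ref); strand <- c(strand, "+"); i <- i + 1L
    } else if (ch == ",") {
      base <- c(base, ref); strand <- c(strand, "-"); i <- i + 1L
    } else if (ch %in% c("A", "C", "G", "T", "N")) {
      base <- c(base, ch); strand <- c(strand, "+"); i <- i + 1L
    } else if (ch %in% c("a", "c", "g", "t", "n")) {
      base <- c(base, toupper(ch)); strand <- c(strand, "-"); i <- i + 1L
    } else if (ch == "*") {
      base <- c(base, "*"); strand <- c(strand, "+"); i <- i + 1L
    } else {
      stop("unexpected pileup symbol '", ch, "'")
    }
  }
  list(base = base, strand = strand)
}

#' Summarize allele observations per site
#'
#' Aggregates observations into one row per (chrom, pos): stranded counts
#' for every base, the alternate allele (the most-supported non-reference
#' base, ties broken lexicographically), reference and alternate depths, and
#' the alternate-allele ratio \code{alt_depth / total_depth}. Sites with no
#' alternate-allele evidence are omitted.
#'
#' @param obs observation data.frame from \code{\link{parse_mpileup}}.
#' @return data.frame with columns \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt}, \code{ref_depth}, \code{alt_depth}, \code{total_depth},
#'   \code{alt_ratio}, \code{alt_fwd}, \code{alt_rev}, \code{third_depth}
#'   (reads supporting neither ref nor alt).
#' @export
summarize_alleles <- function(obs) {
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      ref_depth = integer(0), alt_depth = integer(0),
                      total_depth = integer(0), alt_ratio = numeric(0),
                      alt_fwd = integer(0), alt_rev = integer(0),
                      third_depth = integer(0), stringsAsFactors = FALSE)
  if (!nrow(obs)) return(empty)
  obs <- obs[obs$base %in% c("A", "C", "G", "T"), , drop = FALSE]
  if (!nrow(obs)) return(empty)
  key <- paste(obs$chrom, obs$pos, sep = ":")
  rows <- lapply(split(seq_len(nrow(obs)), key), function(idx) {
    o <- obs[idx, ]
    ref <- o$ref[1]
    cnt <- table(factor(o$base, levels = c("A", "C", "G", "T")))
    altc <- cnt[setdiff(names(cnt), ref)]
    if (sum(altc) == 0) return(NULL)
    alt <- names(altc)[altc == max(altc)][1]   # lexicographic tie-break
    total <- nrow(o)
    data.frame(chrom = o$chrom[1], pos = o$pos[1], ref = ref, alt = alt,
               ref_depth = as.integer(cnt[ref]),
               alt_depth = as.integer(cnt[alt]),
               total_depth = total,
               alt_ratio = as.integer(cnt[alt]) / total,
               alt_fwd = sum(o$base == alt & o$strand == "+"),
               alt_rev = sum(o$base == alt & o$strand == "-"),
               third_depth = total - as.integer(cnt[ref]) - as.integer(cnt[alt]),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$pos), ]
  rownames(out) <- NULL
  out
}
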