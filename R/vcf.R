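#' Write eSNV calls as minimal VCF 4.2
#'
#' One record per call with INFO fields GENE, CSQ (consequence), ALTD
#' (alternate read depth), DP (total depth), CONF (high/low) and SAMPLE.
#'
#' @param calls data.frame with \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt}, \code{gene}, \code{consequence}, \code{alt_depth},
#'   \code{total_depth}, \code{confidence} and optionally \code{sample}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_esnv_vcf <- function(calls, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
           "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Coding consequence\">",
           "##INFO=<ID=ALTD,Number=1,Type=Integer,Description=\"Alternate allele read depth\">",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
           "##INFO=<ID=CONF,Number=1,Type=String,Description=\"Call confidence\">",
           "##INFO=<ID=SAMPLE,Number=1,Type=String,Description=\"Sample id\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- character(0)
  if (nrow(calls)) {
    smp <- if ("sample" %in% names(calls)) calls$sample else
           if ("samples" %in% names(calls)) calls$samples else NA
    ad <- if ("alt_depth" %in% names(calls)) calls$alt_depth else NA
    dp <- if ("total_depth" %in% names(calls)) calls$total_depth else NA
    cf <- if ("confidence" %in% names(calls)) calls$confidence else "high"
    info <- sprintf("GENE=%s;CSQ=%s;ALTD=%s;DP=%s;CONF=%s;SAMPLE=%s",
                    calls$gene, calls$consequence, ad, dp, cf, smp)
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                    calls$chrom, calls$pos, calls$ref, calls$alt, info)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a minimal eSNV VCF back into a call table
#'
#' Inverse of \code{\link{write_esnv_vcf}} for its own dialect:
#' \code{read_esnv_vcf(write_esnv_vcf(calls))} recovers the written fields.
#'
#' @param path VCF path.
#' @return data.frame with \code{chrom}, \code{pos}, \code{ref}, \code{alt},
#'   \code{gene}, \code{consequence}, \code{alt_depth}, \code{total_depth},
#'   \code{confidence}, \code{sample}.
#' @export
read_esnv_vcf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      gene = character(0), consequence = character(0),
                      alt_depth = integer(0), total_depth = integer(0),
                      confidence = character(0), sample = character(0),
                      stringsAsFactors = FALSE))
  }
  f <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  get_info <- function(info, tag) {
    m <- regmatches(info, regexpr(paste0("(^|;)", tag, "=[^;]*"), info))
    ifelse(lengths(regmatches(info, gregexpr(paste0(tag, "="), info))) > 0,
           sub(paste0(".*", tag, "="), "", m), NA_character_)
  }
  info <- f[, 8]
  data.frame(chrom = f[, 1], pos = as.integer(f[, 2]), ref = f[, 4],
             alt = f[, 5],
             gene = vapply(info, get_info, character(1), "GENE",
                           USE.NAMES = FALSE),
             consequence = vapply(info, get_info, character(1), "CSQ",
                                  USE.NAMES = FALSE),
             alt_depth = as.integer(vapply(info, get_info, character(1),
                                           "ALTD", USE.NAMES = FALSE)),
             total_depth = as.integer(vapply(info, get_info, character(1),
                                             "DP", USE.NAMES = FALSE)),
             confidence = vapply(info, get_info, character(1), "CONF",
                                 USE.NAMES = FALSE),
             sample = vapply(info, get_info, character(1), "SAMPLE",
                             USE.NAMES = FALSE),
             stringsAsFactors = FALSE)
}
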