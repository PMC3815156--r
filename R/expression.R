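#' Mode normalization of a count matrix
#'
#' Rescales each sample so that the mode of its per-gene log2 ratios to a
#' pseudo-reference is zero. The pseudo-reference is the per-gene geometric
#' mean across samples; each sample's scale factor is 2 raised to the
#' kernel-density mode (Gaussian kernel, Silverman bandwidth) of
#' \code{log2(sample/reference)} over genes with nonzero counts in both the
#' sample and the reference. This recovers planted global scalings: a sample
#' whose counts are uniformly doubled gets a factor close to 2.
#'
#' @param counts integer matrix, genes x samples (rownames = gene ids,
#'   colnames = sample ids).
#' @return A list of class \code{"normalized_matrix"} with elements
#'   \code{values} (counts divided by the per-sample factor),
#'   \code{scale_factors} (named numeric), \code{log_base = 2},
#'   \code{offset = 1}.
#' @export
mode_normalize <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  zero_samples <- colSums(counts) == 0
  if (any(zero_samples)) {
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[zero_samples], collapse = ", "))
  }
  # geometric-mean pseudo-reference over genes expressed in every sample;
  # fall back to genes nonzero in the individual sample for the ratio set
  lg <- log2(counts)
  lg[!is.finite(lg)] <- NA
  ref <- rowMeans(lg, na.rm = TRUE)          # log2 geometric mean over nonzero
  factors <- vapply(seq_len(ncol(counts)), function(j) {
    ok <- counts[, j] > 0 & is.finite(ref)
    if (sum(ok) < 2L) {
      stop("sample ", colnames(counts)[j],
           " shares too few nonzero genes with the reference")
    }
    ratios <- log2(counts[ok, j]) - ref[ok]
    d <- stats::density(ratios, bw = "nrd0")
    2^d$x[which.max(d$y)]
  }, numeric(1))
  # report factors relative to the median sample: the typical sample keeps
  # scale 1 and a globally doubled sample gets factor ~2; this also makes
  # normalization idempotent (re-run factors ~1)
  factors <- factors / stats::median(factors)
  names(factors) <- colnames(counts)
  structure(
    list(values = sweep(counts, 2, factors, "/"),
         scale_factors = factors, log_base = 2, offset = 1),
    class = "normalized_matrix")
}

#' Filter genes by per-group median expression
#'
#' Keeps exactly the genes whose within-group median raw count is strictly
#' greater than \code{threshold} (default 16 reads) in at least one group.
#' Genes near or below this depth are treated as below the limit of reliable
#' detection.
#'
#' @param counts matrix, genes x samples.
#' @param groups factor or character vector of group labels, one per sample.
#' @param threshold numeric; a gene must exceed this median in >= 1 group.
#' @return The row-subset of \code{counts} passing the filter.
#' @export
filter_low_expression <- function(counts, groups, threshold = 16) {
  counts <- as.matrix(counts)
  groups <- as.character(groups)
  stopifnot(length(groups) == ncol(counts))
  keep <- apply(counts, 1, function(x) {
    any(tapply(x, groups, stats::median) > threshold)
  })
  counts[keep, , drop = FALSE]
}

#' Dunnett-Tukey-Kramer pairwise multiple comparisons
#'
#' All-pairwise comparisons of k group means under unequal variances and
#' unequal sample sizes. For a pair (i, j) the standard error is
#' \code{sqrt(s_i^2/n_i + s_j^2/n_j)}, degrees of freedom are
#' Welch-Satterthwaite, the statistic \code{q = sqrt(2) * |m_i - m_j| / se}
#' is referred to the studentized range distribution with \code{k} means, and
#' the simultaneous confidence interval half-width is
#' \code{qtukey(1 - alpha, k, df) / sqrt(2) * se}. With k = 2 the p-value
#' coincides with the two-sided Welch t-test.
#'
#' Degenerate pairs with zero variance in both groups get p = 1 when the
#' means are equal and p = 0 otherwise.
#'
#' @param values named list of numeric vectors, one per group (>= 2 values
#'   each), or a numeric vector plus \code{groups}.
#' @param groups optional group labels when \code{values} is a vector.
#' @param alpha simultaneous confidence level for the intervals.
#' @return data.frame with one row per unordered group pair: \code{group1},
#'   \code{group2}, \code{diff} (mean1 - mean2), \code{se}, \code{df},
#'   \code{q_stat}, \code{p}, \code{ci_low}, \code{ci_high}.
#' @export
dtk_pairwise <- function(values, groups = NULL, alpha = 0.05) {
  if (!is.list(values)) {
    stopifnot(!is.null(groups), length(groups) == length(values))
    values <- split(as.numeric(values), as.character(groups))
  }
  k <- length(values)
  if (k < 2) stop("need at least 2 groups")
  n <- vapply(values, length, integer(1))
  if (any(n < 2)) stop("need >= 2 observations per group")
  m  <- vapply(values, mean, numeric(1))
  s2 <- vapply(values, stats::var, numeric(1))
  gn <- names(values)
  pairs <- utils::combn(k, 2)
  out <- lapply(seq_len(ncol(pairs)), function(c_) {
    i <- pairs[1, c_]; j <- pairs[2, c_]
    vi <- s2[i] / n[i]; vj <- s2[j] / n[j]
    se <- sqrt(vi + vj)
    diff <- m[i] - m[j]
    if (se == 0) {
      p <- if (diff == 0) 1 else 0
      return(data.frame(group1 = gn[i], group2 = gn[j], diff = diff,
                        se = 0, df = NA_real_, q_stat = if (diff == 0) 0 else Inf,
                        p = p, ci_low = diff, ci_high = diff,
                        stringsAsFactors = FALSE))
    }
    df <- se^4 / (vi^2 / (n[i] - 1) + vj^2 / (n[j] - 1))
    q  <- sqrt(2) * abs(diff) / se
    # for k = 2 the studentized-range tail reduces exactly to the two-sided
    # t tail, which the t CDF evaluates more accurately than ptukey
    p  <- if (k == 2) 2 * stats::pt(-q / sqrt(2), df = df) else
      stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
    hw <- stats::qtukey(1 - alpha, nmeans = k, df = df) / sqrt(2) * se
    data.frame(group1 = gn[i], group2 = gn[j], diff = diff, se = se,
               df = df, q_stat = q, p = p,
               ci_low = diff - hw, ci_high = diff + hw,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Call genes specific to one group
#'
#' Runs \code{\link{dtk_pairwise}} per gene on \code{log2(normalized + 1)}
#' values and flags the genes for which the target group's mean differs from
#' every other group at \code{p < alpha} in all (k - 1) pairwise comparisons.
#'
#' @param values matrix of normalized expression (genes x samples); log2(x+1)
#'   is applied internally when \code{log_transform} is TRUE.
#' @param groups group label per sample.
#' @param target_group the group whose specificity is tested (e.g. "HER2").
#' @param alpha per-comparison significance threshold (default 0.05).
#' @param log_transform apply log2(x + 1) first (default TRUE; set FALSE for
#'   inputs already on a ratio or log scale).
#' @return data.frame, one row per gene: \code{gene}, per-pair p-value
#'   columns \code{p_<other>}, \code{p_max} (largest of the target-vs-other
#'   p-values), \code{direction} (+1 if the target mean exceeds the pooled
#'   mean of the other groups), \code{is_DE}.
#' @export
call_group_specific <- function(values, groups, target_group = "HER2",
                                alpha = 0.05, log_transform = TRUE) {
  values <- as.matrix(values)
  groups <- as.character(groups)
  stopifnot(length(groups) == ncol(values))
  if (!target_group %in% groups) stop("target group not present: ", target_group)
  if (log_transform) values <- log2(values + 1)
  others <- setdiff(unique(groups), target_group)
  res <- lapply(rownames(values), function(g) {
    x <- values[g, ]
    dtk <- dtk_pairwise(split(x, groups))
    ptarget <- vapply(others, function(o) {
      row <- dtk$group1 == target_group & dtk$group2 == o |
             dtk$group2 == target_group & dtk$group1 == o
      if (!any(row)) stop("missing pair ", target_group, " vs ", o)
      dtk$p[row]
    }, numeric(1))
    dir <- sign(mean(x[groups == target_group]) - mean(x[groups != target_group]))
    c(ptarget, p_max = max(ptarget), direction = dir)
  })
  res <- do.call(rbind, res)
  out <- data.frame(gene = rownames(values), res, row.names = NULL,
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(out)[2:(1 + length(others))] <- paste0("p_", others)
  out$is_DE <- out$p_max < alpha
  out
}
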