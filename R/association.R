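#' Spearman rank correlation against drug response
#'
#' Rank correlation (midranks for ties) between a gene's expression and
#' per-line EC50 values. The two-sided p-value uses the t approximation
#' \code{t = rho * sqrt((n - 2) / (1 - rho^2))} on n - 2 df; for n <= 8 an
#' exact permutation p over all n! orderings is available. Being rank-based,
#' the statistic is invariant to strictly monotone transforms of either
#' input (so log-scaling the EC50 is inert).
#'
#' @param expr numeric vector of expression values.
#' @param response numeric vector of EC50 (or any response) values.
#' @param exact compute the exact permutation p (only for n <= 8).
#' @return list: \code{rho}, \code{p}, \code{n}.
#' @export
spearman_vs_response <- function(expr, response, exact = FALSE) {
  ok <- !is.na(expr) & !is.na(response)
  expr <- expr[ok]; response <- response[ok]
  n <- length(expr)
  if (n < 5) stop("need >= 5 paired observations")
  if (stats::sd(expr) == 0 || stats::sd(response) == 0) {
    stop("constant input: rank correlation undefined")
  }
  rx <- rank(expr); ry <- rank(response)
  rho <- stats::cor(rx, ry)
  if (exact) {
    if (n > 8) stop("exact permutation p only for n <= 8")
    perms <- .permutations(n)
    rhos <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else if (abs(rho) >= 1) {
    p <- 0
  } else {
    t <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(t), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Spearman p from a reported correlation coefficient
#'
#' Recomputes the two-sided t-approximation p-value for a given rho and n —
#' useful for checking published correlation tables.
#'
#' @param rho rank correlation coefficient.
#' @param n number of paired observations.
#' @return two-sided p-value.
#' @export
spearman_p_from_rho <- function(rho, n) {
  t <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(-abs(t), df = n - 2)
}

#' Monte Carlo null for correlated-panel process coherence
#'
#' Evaluates how often a random panel of \code{panel_size} genes would, by
#' chance, contain at least \code{n_genes} genes that correlate with the
#' response at p < alpha while all sharing one annotation term (a "single
#' broad biological process"). For each simulation a panel is drawn without
#' replacement, per-gene Spearman p-values are computed, and the maximum
#' number of significant genes sharing any single term is recorded.
#'
#' @param expr gene x sample expression matrix.
#' @param response per-sample response vector (e.g. EC50).
#' @param annotation named list: term -> gene vector.
#' @param panel_size genes per simulated panel.
#' @param n_genes observed count to beat (e.g. 6 genes on one process).
#' @param n_sims number of simulations.
#' @param alpha per-gene significance threshold.
#' @param seed RNG seed.
#' @return list: \code{prob} (empirical probability of >= n_genes coherent
#'   significant genes), \code{counts} (per-sim maxima),
#'   \code{mean_significant} (mean significant genes per panel).
#' @export
random_panel_simulation <- function(expr, response, annotation,
                                    panel_size = 244, n_genes = 6,
                                    n_sims = 1000, alpha = 0.05, seed = 1) {
  expr <- as.matrix(expr)
  if (panel_size > nrow(expr)) stop("panel_size exceeds gene universe")
  set.seed(seed)
  genes <- rownames(expr)
  # precompute per-gene p once: panels reuse the same per-gene statistics
  pvals <- vapply(genes, function(g) {
    spearman_vs_response(expr[g, ], response)$p
  }, numeric(1))
  term_genes <- lapply(annotation, function(gs) intersect(toupper(gs), genes))
  counts <- numeric(n_sims)
  nsig <- numeric(n_sims)
  for (s in seq_len(n_sims)) {
    panel <- sample(genes, panel_size)
    sig <- panel[pvals[panel] < alpha]
    nsig[s] <- length(sig)
    counts[s] <- if (!length(sig)) 0 else
      max(0, vapply(term_genes, function(tg) sum(sig %in% tg), numeric(1)))
  }
  list(prob = mean(counts >= n_genes), counts = counts,
       mean_significant = mean(nsig))
}

#' Cox partial-likelihood score statistic at beta = 0
#'
#' Univariable proportional-hazards score test with Breslow tie handling:
#' \code{U = sum over event times [sum of x over events - d * mean(x | risk
#' set)]}, \code{I = sum d * var(x | risk set)} (population variance), and
#' the statistic is \code{U / sqrt(I)}, asymptotically N(0,1) under the
#' null. A positive value means higher expression associates with higher
#' hazard (shorter time to event).
#'
#' @param x numeric covariate (gene expression per patient).
#' @param time time to event or censoring (> 0).
#' @param event 1 = event, 0 = censored.
#' @return signed score statistic (0 when the covariate is constant).
#' @export
cox_score <- function(x, time, event) {
  stopifnot(length(x) == length(time), length(x) == length(event),
            all(time > 0), all(event %in% c(0, 1)))
  if (sum(event) == 0) stop("no events")
  if (stats::sd(x) == 0) return(0)
  layout <- .cox_layout(time, event)
  .cox_score_core(x[layout$ord], layout)
}

# shared risk-set bookkeeping for one (time, event) configuration: sorted
# order, first sorted index of each distinct event time, tie multiplicities,
# and the event positions grouped by time
.cox_layout <- function(time, event) {
  ord <- order(time)
  ts <- time[ord]; es <- event[ord]
  n <- length(ts)
  ev <- which(es == 1)
  et <- ts[ev]
  starts <- which(!duplicated(et))
  ends <- c(starts[-1] - 1L, length(et))
  list(ord = ord, n = n, ev = ev,
       idx = match(et[starts], ts),       # risk-set start per event time
       d = ends - starts + 1L, starts = starts, ends = ends)
}

# Breslow score statistic for a covariate already sorted by the layout
.cox_score_core <- function(xs, layout) {
  n <- layout$n
  sx <- rev(cumsum(rev(xs)))
  sx2 <- rev(cumsum(rev(xs * xs)))
  csx <- cumsum(xs[layout$ev])
  sum_ev_x <- csx[layout$ends] -
    c(0, csx[layout$ends[-length(layout$ends)]])
  nr <- n - layout$idx + 1
  mu <- sx[layout$idx] / nr
  U <- sum(sum_ev_x - layout$d * mu)
  I <- sum(layout$d * (sx2[layout$idx] / nr - mu^2))
  if (I <= 0) return(0)
  U / sqrt(I)
}

# score statistics for every row of X against one outcome
.cox_scores <- function(X, time, event) {
  layout <- .cox_layout(time, event)
  apply(X[, layout$ord, drop = FALSE], 1, .cox_score_core, layout = layout)
}

#' Maxmean gene-set analysis of Cox gene scores
#'
#' For each gene set, the maxmean statistic is the larger in magnitude of
#' the mean positive part and the mean negative part of the member genes'
#' scores (sign retained). Gene scores are restandardized against the
#' catalogue of all scored genes (centered and scaled by their overall mean
#' and sd) before averaging, within the observed data and within every
#' permutation. Significance comes from permuting the per-patient outcome
#' (time, event) pairs and recomputing the Cox scores, and the FDR is the
#' permutation-based plug-in estimate: the average number of null sets
#' exceeding a set's |score| divided by the observed count.
#'
#' @param expr gene x patient expression matrix.
#' @param time,event survival outcome per patient.
#' @param sets named list: set name -> gene vector.
#' @param n_perms number of outcome permutations.
#' @param seed RNG seed.
#' @return data.frame: \code{set}, \code{n_genes}, \code{score}, \code{p},
#'   \code{FDR}, \code{direction} ("positive"/"negative"). Sets with < 2
#'   scored genes are skipped with a warning.
#' @export
gsa_maxmean <- function(expr, time, event, sets, n_perms = 500, seed = 1) {
  expr <- as.matrix(expr)
  genes <- rownames(expr)
  sets <- lapply(sets, function(g) intersect(toupper(g), toupper(genes)))
  small <- lengths(sets) < 2
  if (any(small)) {
    warning("skipping set(s) with < 2 scored genes: ",
            paste(names(sets)[small], collapse = ", "))
    sets <- sets[!small]
  }
  if (!length(sets)) stop("no usable gene sets")
  idx <- lapply(sets, function(g) match(g, toupper(genes)))

  const <- apply(expr, 1, stats::sd) == 0
  score_genes <- function(tt, ee) {
    z <- .cox_scores(expr, tt, ee)
    z[const] <- 0
    z
  }
  maxmean <- function(z) {
    sp <- mean(pmax(z, 0)); sn <- mean(pmax(-z, 0))
    if (sp >= sn) sp else -sn
  }
  restd <- function(z) {
    s <- stats::sd(z)
    if (s == 0) z * 0 else (z - mean(z)) / s
  }
  z_obs <- score_genes(time, event)
  if (all(z_obs == 0)) {
    zr_obs <- z_obs
  } else {
    zr_obs <- restd(z_obs)
  }
  s_obs <- vapply(idx, function(i) maxmean(zr_obs[i]), numeric(1))

  set.seed(seed)
  n <- length(time)
  s_perm <- matrix(NA_real_, n_perms, length(idx))
  for (b in seq_len(n_perms)) {
    pp <- sample.int(n)
    zb <- score_genes(time[pp], event[pp])
    zrb <- if (all(zb == 0)) zb else restd(zb)
    s_perm[b, ] <- vapply(idx, function(i) maxmean(zrb[i]), numeric(1))
  }
  p <- vapply(seq_along(idx), function(j) {
    (1 + sum(abs(s_perm[, j]) >= abs(s_obs[j]))) / (1 + n_perms)
  }, numeric(1))
  fdr <- vapply(seq_along(idx), function(j) {
    thr <- abs(s_obs[j])
    exp_null <- mean(rowSums(abs(s_perm) >= thr))
    obs <- sum(abs(s_obs) >= thr)
    min(1, exp_null / max(obs, 1))
  }, numeric(1))
  data.frame(set = names(sets), n_genes = lengths(sets),
             score = s_obs, p = p, FDR = fdr,
             direction = ifelse(s_obs >= 0, "positive", "negative"),
             row.names = NULL, stringsAsFactors = FALSE)
}
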