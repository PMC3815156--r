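#' Generate drug-response and survival phenotypes linked to expression
#'
#' EC50 values are a monotone (log-linear) function of the mean expression
#' of the selected response genes plus Gaussian noise; survival times are
#' exponential with log-hazard proportional to the mean expression of the
#' outcome module, with uniform censoring.
#'
#' @param expr gene x sample expression matrix (any positive scale; used
#'   as-is after per-gene standardization of the driver genes).
#' @param config \code{\link{simulation_config}} (provides the seed).
#' @param response_genes genes driving EC50 (subset of rownames(expr)).
#' @param outcome_genes genes driving hazard.
#' @param ec50_effect slope of log EC50 per SD of driver-gene mean
#'   expression (0 = null).
#' @param hazard_effect log hazard ratio per SD of outcome-module mean
#'   expression (0 = null).
#' @param ec50_noise_sd Gaussian noise SD on log EC50.
#' @param censor_frac expected fraction of censored patients.
#' @return list: \code{ec50} (data.frame sample, ec50), \code{survival}
#'   (data.frame sample, time, event), \code{truth} (list of the driver
#'   gene sets and effects).
#' @export
generate_phenotypes <- function(expr, config,
                                response_genes = character(0),
                                outcome_genes = character(0),
                                ec50_effect = 1, hazard_effect = 1,
                                ec50_noise_sd = 0.3, censor_frac = 0.3) {
  stopifnot(inherits(config, "simulation_config"))
  expr <- as.matrix(expr)
  if (ec50_effect != 0 && !length(response_genes)) {
    stop("nonzero ec50_effect with empty response_genes")
  }
  if (hazard_effect != 0 && !length(outcome_genes)) {
    stop("nonzero hazard_effect with empty outcome_genes")
  }
  missing <- setdiff(c(response_genes, outcome_genes), rownames(expr))
  if (length(missing)) {
    stop("driver gene(s) absent from expr: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  set.seed(config$seed + 4L)
  n <- ncol(expr)
  module_score <- function(genes) {
    if (!length(genes)) return(rep(0, n))
    as.numeric(scale(colMeans(expr[genes, , drop = FALSE])))
  }
  lp_ec50 <- ec50_effect * module_score(response_genes)
  ec50 <- exp(lp_ec50 + stats::rnorm(n, 0, ec50_noise_sd))
  lp_haz <- hazard_effect * module_score(outcome_genes)
  time <- stats::rexp(n, rate = 0.05 * exp(lp_haz))
  if (censor_frac > 0) {
    # uniform censoring calibrated to the target fraction
    cmax <- stats::quantile(time, probs = min(1, 2 * (1 - censor_frac)))
    ctime <- stats::runif(n, 0, 2 * as.numeric(cmax))
    event <- as.integer(time <= ctime)
    obs_time <- pmin(time, ctime)
  } else {
    event <- rep(1L, n)
    obs_time <- time
  }
  obs_time <- pmax(obs_time, 1e-6)
  list(ec50 = data.frame(sample = colnames(expr), ec50 = ec50,
                         stringsAsFactors = FALSE),
       survival = data.frame(sample = colnames(expr), time = obs_time,
                             event = event, stringsAsFactors = FALSE),
       truth = list(response_genes = response_genes,
                    outcome_genes = outcome_genes,
                    ec50_effect = ec50_effect,
                    hazard_effect = hazard_effect))
}
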