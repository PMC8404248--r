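#' Simulate coverage cells directly from the hierarchical trend model
#'
#' Generates (group, year) binomial coverage cells from the same model
#' family the trend fitter assumes — group intercepts and slopes drawn from
#' normal population distributions on the logit scale, optional common
#' predictor effects — for parameter-recovery and calibration studies with
#' known ground truth.
#'
#' @param n_groups number of groups (e.g. governorates).
#' @param years survey years.
#' @param n_per_cell binomial denominator per cell.
#' @param mu_alpha,sd_alpha population mean / sd of the group intercepts
#'   (logit scale, at the 2009 centring point).
#' @param mu_beta,sd_beta population mean / sd of the group slopes (logit
#'   per decade).
#' @param theta optional named predictor coefficients; predictor values are
#'   drawn standard-normal per (group, year) and returned.
#' @param level stratum level label stamped on the cells.
#' @param seed integer seed.
#' @return a `uhc_coverage`-shaped data.frame (with binomial `se` and
#'   `n_eff = n`); generating parameters in `attr(, "ground_truth")`.
#' @export
simulate_coverage_cells <- function(n_groups = 18,
                                    years = c(2000, 2006, 2011, 2018),
                                    n_per_cell = 500,
                                    mu_alpha = -0.5, sd_alpha = 0.4,
                                    mu_beta = 0.5, sd_beta = 0.15,
                                    theta = NULL, level = "governorate",
                                    seed = 1L) {
  set.seed(fan_seed(seed, "coverage-cells"))
  d <- expand.grid(stratum = as.character(seq_len(n_groups)), year = years,
                   stringsAsFactors = FALSE)
  alpha <- stats::rnorm(n_groups, mu_alpha, sd_alpha)
  beta <- stats::rnorm(n_groups, mu_beta, sd_beta)
  gi <- as.integer(d$stratum)
  eta <- alpha[gi] + beta[gi] * time_decades(d$year)
  xmat <- NULL
  if (!is.null(theta)) {
    xmat <- matrix(stats::rnorm(nrow(d) * length(theta)), ncol = length(theta),
                   dimnames = list(NULL, names(theta)))
    eta <- eta + drop(xmat %*% unlist(theta))
  }
  p_true <- invlogit(eta)
  yy <- stats::rbinom(nrow(d), n_per_cell, p_true)
  p <- yy / n_per_cell
  se <- sqrt(pmax(p * (1 - p), 1e-8) / n_per_cell)
  out <- data.frame(indicator = "SIM", year = d$year, level = level,
                    stratum = d$stratum, p = p, se = se,
                    n_eff = n_per_cell, n = n_per_cell,
                    pop_share = 1 / n_groups, missing = FALSE)
  if (!is.null(xmat)) for (v in colnames(xmat)) out[[paste0("x_", v)]] <- xmat[, v]
  class(out) <- c("uhc_coverage", "data.frame")
  attr(out, "ground_truth") <- list(alpha = alpha, beta = beta,
                                    mu_alpha = mu_alpha, sd_alpha = sd_alpha,
                                    mu_beta = mu_beta, sd_beta = sd_beta,
                                    theta = theta, p_true = p_true,
                                    x = xmat, seed = seed)
  out
}
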