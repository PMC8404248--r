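## ---------------------------------------------------------------------------
## Bayesian hierarchical trend model and 2030 projection
##
## Likelihood: binomial on design-effective counts with a logit link,
##   logit(p[g,t]) = alpha_g + beta_g * t + sum_k theta_k x[k,g,t]
## with t in decades centred at 2009.  Group intercepts and slopes are drawn
## from normal population distributions with vague hyperpriors; predictor
## coefficients are shared across groups.  Sampled with JAGS via rjags.
## ---------------------------------------------------------------------------

time_decades <- function(year) (year - 2009) / 10

## split R-hat: each chain halved, potential scale reduction across the
## resulting 2C half-chains
split_rhat <- function(x) {
  ## x: iterations x chains matrix
  n <- nrow(x)
  if (n < 4) return(NA_real_)
  half <- floor(n / 2)
  halves <- cbind(x[seq_len(half), , drop = FALSE],
                  x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(halves); nn <- nrow(halves)
  mu <- colMeans(halves)
  s2 <- apply(halves, 2, stats::var)
  W <- mean(s2)
  B <- nn * stats::var(mu)
  if (W <= 0) return(if (B <= 1e-12) 1 else Inf)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

jags_trend_model <- function(G, K) {
  lik_x <- if (K > 0) " + inprod(theta[1:K], x[i, 1:K])" else ""
  hier <- if (G > 1) "
  for (j in 1:G) {
    alpha[j] ~ dnorm(mu_a, tau_a)
    beta[j] ~ dnorm(mu_b, tau_b)
  }
  mu_a ~ dnorm(0, 1.0E-4)
  mu_b ~ dnorm(0, 1.0E-4)
  sig_a ~ dnorm(0, 0.04) T(0,)
  sig_b ~ dnorm(0, 0.04) T(0,)
  tau_a <- pow(sig_a, -2)
  tau_b <- pow(sig_b, -2)" else "
  alpha[1] ~ dnorm(0, 1.0E-4)
  beta[1] ~ dnorm(0, 1.0E-4)"
  theta <- if (K > 0) "
  for (k in 1:K) { theta[k] ~ dnorm(0, 1.0E-4) }" else ""
  paste0("model {
  for (i in 1:N) {
    y[i] ~ dbin(p[i], n[i])
    logit(p[i]) <- alpha[g[i]] + beta[g[i]] * t[i]", lik_x, "
  }", hier, theta, "
}")
}

## national average of a (possibly subnational) predictor series
nationalize <- function(df) {
  stats::aggregate(value ~ variable + year, df, mean)
}

#' Project predictor series to a horizon year
#'
#' Bayesian linear trend per series with a flat conjugate prior, sampled in
#' closed form (normal-inverse-chi-squared posterior); strictly positive
#' series are modelled on the log scale so projections stay positive, other
#' series on the identity scale with projections truncated at zero and
#' flagged.  Series with fewer than three observed points fall back to
#' last-observation-carried-forward with a warning.  The projection
#' uncertainty is retained as posterior draws of the trend mean and is
#' carried into coverage projections.
#'
#' @param series long predictor data.frame as from [simulate_predictors()].
#' @param horizon last projection year.
#' @param n_draws posterior draws per series.
#' @param seed integer seed.
#' @return object of class `uhc_predproj`: `$series` (observed rows plus
#'   projected rows flagged `observed = FALSE`, `value` = posterior median
#'   with `lo`/`hi`), `$draws` (per-series draw matrices), `$horizon`.
#' @export
project_predictors <- function(series, horizon = 2030, n_draws = 1000,
                               seed = 1L) {
  stopifnot(all(c("variable", "year", "value") %in% names(series)))
  if (is.null(series$governorate)) series$governorate <- NA_integer_
  if (is.null(series$observed)) series$observed <- TRUE
  set.seed(fan_seed(seed, "project-predictors"))
  obs <- series[series$observed, ]
  keys <- unique(obs[, c("variable", "governorate")])
  draws <- list()
  out <- list()
  for (r in seq_len(nrow(keys))) {
    v <- keys$variable[r]; g <- keys$governorate[r]
    sel <- obs$variable == v &
      (is.na(g) & is.na(obs$governorate) |
         !is.na(g) & !is.na(obs$governorate) & obs$governorate == g)
    s <- obs[sel, ]
    s <- s[order(s$year), ]
    yrs_new <- setdiff(seq(min(s$year), horizon), s$year)
    yrs_new <- yrs_new[yrs_new > max(s$year)]
    key <- paste(v, g, sep = "\r")
    if (length(yrs_new) == 0) next
    if (nrow(s) < 3) {
      warning("series ", v, " has fewer than 3 points; ",
              "carrying last observation forward", call. = FALSE)
      dm <- matrix(s$value[nrow(s)], n_draws, length(yrs_new))
    } else {
      uselog <- all(s$value > 0)
      yv <- if (uselog) log(s$value) else s$value
      X <- cbind(1, s$year - 2000)
      XtXi <- solve(crossprod(X))
      bhat <- XtXi %*% crossprod(X, yv)
      res <- yv - X %*% bhat
      df_res <- nrow(s) - 2
      s2 <- sum(res^2) / df_res
      Xp <- cbind(1, yrs_new - 2000)
      if (s2 < 1e-14) {
        dm <- matrix(rep(drop(Xp %*% bhat), each = n_draws), n_draws)
      } else {
        sig2 <- s2 * df_res / stats::rchisq(n_draws, df_res)
        L <- chol(XtXi)
        bdraw <- matrix(stats::rnorm(2 * n_draws), n_draws) %*% L *
          sqrt(sig2) + rep(drop(bhat), each = n_draws)
        dm <- bdraw %*% t(Xp)
      }
      if (uselog) dm <- exp(dm) else dm <- pmax(dm, 0)
    }
    colnames(dm) <- yrs_new
    draws[[key]] <- dm
    qs <- apply(dm, 2, stats::quantile, probs = c(0.5, ci_probs))
    out[[length(out) + 1L]] <- data.frame(
      variable = v, governorate = g, year = yrs_new, value = qs[1, ],
      lo = qs[2, ], hi = qs[3, ], observed = FALSE)
  }
  obs$lo <- obs$value; obs$hi <- obs$value
  res <- rbind(obs[, c("variable", "governorate", "year", "value", "lo",
                       "hi", "observed")],
               do.call(rbind, out))
  rownames(res) <- NULL
  structure(list(series = res, draws = draws, horizon = horizon),
            class = "uhc_predproj")
}

#' @export
print.uhc_predproj <- function(x, ...) {
  cat("Predictor projection to", x$horizon, "\n")
  print(utils::head(x$series[!x$series$observed, ], 6))
  invisible(x)
}

## standardized predictor design pieces for one fit: values at observed
## survey years (fixed) and projected draws (uncertain)
build_predictor_design <- function(predictors, level, groups, years_obs,
                                   horizon, n_mcmc_draws, seed) {
  if (is.null(predictors)) return(NULL)
  if (inherits(predictors, "uhc_predproj")) {
    proj <- predictors
  } else {
    proj <- project_predictors(predictors, horizon = horizon,
                               seed = fan_seed(seed, "trend-pred"))
  }
  ser <- proj$series
  gov_level <- level == "governorate"
  if (!gov_level) {
    ## subnational series averaged to a national series for non-governorate
    ## aggregation levels
    obs_nat <- nationalize(ser[ser$observed, ])
  }
  vars <- unique(ser$variable)
  K <- length(vars)
  std <- lapply(vars, function(v) {
    o <- ser[ser$observed & ser$variable == v, ]
    c(mu = mean(o$value), sd = max(stats::sd(o$value), 1e-12))
  })
  names(std) <- vars
  get_obs <- function(v, gov, year) {
    if (gov_level && any(!is.na(ser$governorate[ser$variable == v]))) {
      o <- ser[ser$observed & ser$variable == v, ]
      val <- o$value[match(paste(gov, year), paste(o$governorate, o$year))]
    } else if (!gov_level) {
      o <- if (exists("obs_nat")) obs_nat else nationalize(ser[ser$observed, ])
      o <- o[o$variable == v, ]
      val <- o$value[match(year, o$year)]
    } else {
      o <- ser[ser$observed & ser$variable == v & is.na(ser$governorate), ]
      val <- o$value[match(year, o$year)]
    }
    (val - std[[v]]["mu"]) / std[[v]]["sd"]
  }
  ## projected draws resampled to align with MCMC draws
  set.seed(fan_seed(seed, "pred-align"))
  get_proj_draws <- function(v, gov, year) {
    keyed <- function(g) proj$draws[[paste(v, g, sep = "\r")]]
    if (gov_level && !is.null(keyed(gov))) {
      dm <- keyed(gov)
    } else if (!is.null(keyed(NA))) {
      dm <- keyed(NA)
    } else {
      ## average the governorate draw matrices
      gs <- grep(paste0("^", v, "\r"), names(proj$draws), value = TRUE)
      if (length(gs) == 0) return(NULL)
      dm <- Reduce(`+`, proj$draws[gs]) / length(gs)
    }
    if (!as.character(year) %in% colnames(dm)) return(NULL)
    idx <- sample.int(nrow(dm), n_mcmc_draws, replace = TRUE)
    (dm[idx, as.character(year)] - std[[v]]["mu"]) / std[[v]]["sd"]
  }
  list(vars = vars, K = K, get_obs = get_obs, get_proj_draws = get_proj_draws,
       max_obs_year = max(ser$year[ser$observed]), proj = proj)
}

#' Fit the hierarchical coverage trend model and project to a horizon
#'
#' Fits, for one indicator at one aggregation level, a Bayesian hierarchical
#' logistic trend model to design-effective binomial counts and projects
#' coverage for every year up to the horizon by pushing (projected)
#' predictor draws through the linear predictor.  Group intercepts and
#' slopes are exchangeable normal; predictor coefficients are common to all
#' groups; priors are vague but proper (normal sd 100 on fixed effects and
#' hyper-means, half-normal sd 5 on hierarchical sds).  Convergence is
#' declared from split R-hat on every monitored parameter.
#'
#' @param cells a `uhc_coverage` table (see [estimate_coverage()]).
#' @param indicator indicator code to fit (needed when `cells` holds
#'   several).
#' @param level aggregation level: `"governorate"`, `"residence"`,
#'   `"quintile"` or `"national"`.
#' @param predictors optional long predictor data.frame or
#'   [project_predictors()] result; `NULL` fits the time-only model.
#' @param horizon last projection year.
#' @param chains,adapt,burnin,iter,thin MCMC settings (defaults: 4 chains,
#'   2000 warm-up, 2000 kept draws each).
#' @param rhat_max convergence threshold on split R-hat.
#' @param seed integer seed; fixes the sampler streams.
#' @return object of class `uhc_trend`.
#' @export
fit_trend <- function(cells, indicator = NULL, level = "governorate",
                      predictors = NULL, horizon = 2030,
                      chains = 4, adapt = 500, burnin = 2000, iter = 2000,
                      thin = 1, rhat_max = 1.05, seed = 1L) {
  stopifnot(is.data.frame(cells))
  if (!is.null(indicator)) cells <- cells[cells$indicator == indicator, ]
  if (!is.null(cells$level)) cells <- cells[cells$level == level, ]
  if (!is.null(cells$missing)) cells <- cells[!cells$missing, ]
  if (length(unique(cells$indicator)) != 1)
    stop("cells must cover exactly one indicator; pass 'indicator='",
         call. = FALSE)
  if (length(unique(cells$year)) < 2)
    stop("need at least 2 survey years", call. = FALSE)
  if (any(!is.finite(cells$n_eff)))
    stop("cells must carry effective denominators", call. = FALSE)
  indicator <- cells$indicator[1]
  cells <- cells[order(cells$stratum, cells$year), ]
  groups <- sort(unique(cells$stratum))
  G <- length(groups)
  gi <- match(cells$stratum, groups)
  n <- pmax(round(cells$n_eff), 1)
  y <- pmin(pmax(round(cells$p * n), 0), n)
  tt <- time_decades(cells$year)
  n_keep <- chains * floor(iter / thin)

  pd <- build_predictor_design(predictors, level, groups,
                               unique(cells$year), horizon, n_keep, seed)
  K <- if (is.null(pd)) 0L else pd$K
  dat <- list(y = y, n = n, g = gi, t = tt, N = length(y))
  if (G > 1) dat$G <- G
  if (K > 0) {
    X <- sapply(pd$vars, function(v)
      pd$get_obs(v, cells$stratum, cells$year))
    X <- matrix(X, ncol = K)
    if (anyNA(X))
      stop("predictor series do not cover all survey years", call. = FALSE)
    zv <- apply(X, 2, stats::sd) < 1e-10
    if (any(zv))
      warning("predictor(s) ", paste(pd$vars[zv], collapse = ", "),
              " have zero variance over the fitted cells; their ",
              "coefficients are not informed by the data", call. = FALSE)
    dat$x <- X
    dat$K <- K
  }
  inits <- lapply(seq_len(chains), function(c)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = fan_seed(seed, paste0("trend-chain-", c))))
  model <- jags_trend_model(G, K)
  jm <- rjags::jags.model(textConnection(model), data = dat,
                          inits = inits, n.chains = chains, n.adapt = adapt,
                          quiet = TRUE)
  stats::update(jm, burnin, progress.bar = "none")
  monitors <- c("alpha", "beta",
                if (G > 1) c("mu_a", "mu_b", "sig_a", "sig_b"),
                if (K > 0) "theta")
  samp <- rjags::coda.samples(jm, monitors, n.iter = iter, thin = thin,
                              progress.bar = "none")
  draws <- do.call(rbind, lapply(samp, as.matrix))
  chain_id <- rep(seq_len(chains), each = nrow(samp[[1]]))
  ## coda drops the bracket on length-1 monitored arrays; normalize
  cn <- colnames(draws)
  cn[cn == "alpha"] <- "alpha[1]"
  cn[cn == "beta"] <- "beta[1]"
  cn[cn == "theta"] <- "theta[1]"
  colnames(draws) <- cn

  ## deviance trace and deviance at the posterior mean, computed from the
  ## package's own binomial likelihood
  nd <- nrow(draws)
  A <- matrix(sapply(seq_len(G), function(j) draws[, sprintf("alpha[%d]", j)]),
              ncol = G)
  B <- matrix(sapply(seq_len(G), function(j) draws[, sprintf("beta[%d]", j)]),
              ncol = G)
  Eta <- A[, gi, drop = FALSE] +
    B[, gi, drop = FALSE] * matrix(tt, nd, length(tt), byrow = TRUE)
  if (K > 0) {
    TH <- matrix(sapply(seq_len(K),
                        function(k) draws[, sprintf("theta[%d]", k)]),
                 ncol = K)
    Eta <- Eta + TH %*% t(dat$x)
  }
  P <- pmin(pmax(invlogit(Eta), 1e-12), 1 - 1e-12)
  Ym <- matrix(y, nd, length(y), byrow = TRUE)
  Nm <- matrix(n, nd, length(n), byrow = TRUE)
  Cm <- matrix(lchoose(n, y), nd, length(y), byrow = TRUE)
  dev_draws <- -2 * rowSums(Ym * log(P) + (Nm - Ym) * log1p(-P) + Cm)
  pm <- colMeans(draws)
  eta_pm <- pm[sprintf("alpha[%d]", gi)] + pm[sprintf("beta[%d]", gi)] * tt
  if (K > 0)
    eta_pm <- eta_pm + drop(dat$x %*% pm[sprintf("theta[%d]", seq_len(K))])
  dev_at_mean <- -2 * sum(stats::dbinom(y, n, invlogit(eta_pm), log = TRUE))

  ## diagnostics
  diag_df <- data.frame(parameter = colnames(draws))
  diag_df$rhat <- vapply(colnames(draws), function(p) {
    split_rhat(matrix(draws[, p], ncol = chains))
  }, numeric(1))
  ess <- try(coda::effectiveSize(samp), silent = TRUE)
  diag_df$ess <- if (inherits(ess, "try-error")) NA_real_
                 else as.numeric(ess[diag_df$parameter])
  converged <- all(diag_df$rhat <= rhat_max, na.rm = TRUE)
  if (!converged)
    warning("trend fit for ", indicator, " (", level,
            ") did not converge (max split R-hat ",
            sprintf("%.3f", max(diag_df$rhat, na.rm = TRUE)),
            "); projections flagged", call. = FALSE)

  ## projections 2000..horizon per group
  years_proj <- seq(min(cells$year, 2000), horizon)
  max_obs <- if (is.null(pd)) max(cells$year) else pd$max_obs_year
  proj <- list()
  for (j in seq_len(G)) {
    eta <- outer(draws[, sprintf("alpha[%d]", j)], rep(1, length(years_proj))) +
      outer(draws[, sprintf("beta[%d]", j)], time_decades(years_proj))
    if (K > 0) {
      for (k in seq_len(K)) {
        v <- pd$vars[k]
        for (ci in seq_along(years_proj)) {
          yr <- years_proj[ci]
          if (yr <= max_obs) {
            xv <- pd$get_obs(v, groups[j], yr)
            if (is.na(xv)) { ## year outside the observed span but not beyond
              xv <- 0
            }
            eta[, ci] <- eta[, ci] + draws[, sprintf("theta[%d]", k)] * xv
          } else {
            xd <- pd$get_proj_draws(v, groups[j], yr)
            if (!is.null(xd))
              eta[, ci] <- eta[, ci] + draws[, sprintf("theta[%d]", k)] * xd
          }
        }
      }
    }
    pp <- invlogit(eta)
    qs <- apply(pp, 2, stats::quantile, probs = c(0.5, ci_probs))
    proj[[j]] <- data.frame(indicator = indicator, level = level,
                            stratum = groups[j], year = years_proj,
                            p = qs[1, ], lo = qs[2, ], hi = qs[3, ],
                            observed = years_proj %in% cells$year)
  }
  projection <- do.call(rbind, proj)
  rownames(projection) <- NULL

  structure(list(indicator = indicator, level = level, groups = groups,
                 draws = draws, chain = chain_id, chains = chains,
                 data = cells, deviance = dev_draws,
                 deviance_at_mean = dev_at_mean,
                 diagnostics = diag_df, converged = converged,
                 rhat_max = rhat_max, projection = projection,
                 predictor_vars = if (K > 0) pd$vars else character(0),
                 horizon = horizon, seed = seed,
                 mcmc = list(chains = chains, adapt = adapt,
                             burnin = burnin, iter = iter, thin = thin),
                 call = match.call()),
            class = "uhc_trend")
}

#' Deviance information criterion of a fitted trend model
#'
#' `DIC = mean deviance + pD` with the effective number of parameters
#' `pD = mean deviance - deviance at the posterior means`.
#'
#' @param fit a `uhc_trend` (or `uhc_determinants`) object.
#' @return list with `dic`, `pd`, `mean_deviance`.
#' @export
compute_dic <- function(fit) {
  if (is.null(fit[["deviance"]]) || is.null(fit[["deviance_at_mean"]]))
    stop("fit carries no deviance trace", call. = FALSE)
  md <- mean(fit$deviance)
  pd <- md - fit$deviance_at_mean
  list(dic = md + pd, pd = pd, mean_deviance = md)
}

#' MCMC convergence report
#'
#' Per-parameter split R-hat and effective sample size with an overall
#' pass/fail against the thresholds.
#'
#' @param fit a fitted `uhc_trend` or `uhc_determinants` object.
#' @param rhat_max maximum acceptable split R-hat.
#' @param ess_min minimum acceptable effective sample size.
#' @return data.frame `parameter`, `rhat`, `ess`, `pass`, with attribute
#'   `overall` (logical).
#' @export
check_convergence <- function(fit, rhat_max = 1.05, ess_min = 400) {
  d <- fit$diagnostics
  d$pass <- d$rhat <= rhat_max & (is.na(d$ess) | d$ess >= ess_min)
  attr(d, "overall") <- all(d$pass, na.rm = TRUE)
  d
}

#' Target-attainment report at the projection horizon
#'
#' For each fitted indicator and stratum: projected median coverage with
#' credible interval at the report year, whether it attains the coverage
#' target, and the percentage-point gap between the distribution extremes
#' of the level (richest minus poorest quintile, or urban minus rural).
#'
#' @param fits a `uhc_trend` object or list of them.
#' @param target coverage target (default the 80% service target).
#' @param year report year.
#' @return data.frame, one row per indicator and stratum.
#' @export
coverage_gap_report <- function(fits, target = 0.80, year = 2030) {
  if (inherits(fits, "uhc_trend")) fits <- list(fits)
  out <- list()
  for (f in fits) {
    pr <- f$projection[f$projection$year == year, ]
    if (nrow(pr) == 0)
      stop("no projection at year ", year, " for ", f$indicator,
           call. = FALSE)
    gap <- NA_real_
    if (f$level == "quintile" && all(c("1", "5") %in% pr$stratum)) {
      gap <- 100 * (pr$p[pr$stratum == "5"] - pr$p[pr$stratum == "1"])
    } else if (f$level == "residence" &&
               all(c("urban", "rural") %in% pr$stratum)) {
      gap <- 100 * (pr$p[pr$stratum == "urban"] - pr$p[pr$stratum == "rural"])
    }
    out[[length(out) + 1L]] <- data.frame(
      indicator = f$indicator, level = f$level, stratum = pr$stratum,
      year = year, p = pr$p, lo = pr$lo, hi = pr$hi,
      attains = pr$p >= target, gap_pp = gap,
      converged = f$converged)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @export
print.uhc_trend <- function(x, ...) {
  cat(sprintf("Hierarchical coverage trend: %s at %s level (%d groups)\n",
              x$indicator, x$level, length(x$groups)))
  cat(sprintf("  %d chains x %d kept draws; converged: %s (max split R-hat %.3f)\n",
              x$chains, nrow(x$draws) / x$chains,
              ifelse(x$converged, "yes", "NO"),
              max(x$diagnostics$rhat, na.rm = TRUE)))
  if (length(x$predictor_vars))
    cat("  predictors:", paste(x$predictor_vars, collapse = ", "), "\n")
  dic <- compute_dic(x)
  cat(sprintf("  DIC %.1f (pD %.1f)\n", dic$dic, dic$pd))
  invisible(x)
}

#' @export
coef.uhc_trend <- function(object, ...) {
  apply(object$draws, 2, stats::median)
}

#' @export
summary.uhc_trend <- function(object, ...) {
  print(object)
  qs <- t(apply(object$draws, 2, stats::quantile,
                probs = c(0.5, ci_probs)))
  colnames(qs) <- c("median", "2.5%", "97.5%")
  pop <- grep("^(mu_|sig_|theta)", rownames(qs))
  if (length(pop)) {
    cat("Population-level parameters:\n")
    print(round(qs[pop, , drop = FALSE], 3))
  }
  invisible(qs)
}

#' @export
predict.uhc_trend <- function(object, years = NULL, ...) {
  pr <- object$projection
  if (!is.null(years)) pr <- pr[pr$year %in% years, ]
  pr
}

#' @export
plot.uhc_trend <- function(x, target = 0.80, ...) {
  pr <- x$projection
  groups <- x$groups
  cols <- grDevices::hcl.colors(max(length(groups), 2), "Dark 2")
  plot(NA, xlim = range(pr$year), ylim = c(0, 1), xlab = "year",
       ylab = "coverage",
       main = sprintf("%s (%s level)", x$indicator, x$level))
  for (j in seq_along(groups)) {
    s <- pr[pr$stratum == groups[j], ]
    graphics::lines(s$year, s$p, col = cols[j], lwd = 2)
    graphics::lines(s$year, s$lo, col = cols[j], lty = 3)
    graphics::lines(s$year, s$hi, col = cols[j], lty = 3)
  }
  graphics::abline(h = target, lty = 2, col = "grey40")
  obs <- x$data
  graphics::points(obs$year, obs$p,
                   col = cols[match(obs$stratum, groups)], pch = 19)
  if (length(groups) <= 8)
    graphics::legend("bottomright", legend = groups, col = cols[seq_along(groups)],
                     lwd = 2, bty = "n", cex = 0.8)
  invisible(x)
}
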