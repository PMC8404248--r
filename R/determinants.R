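## ---------------------------------------------------------------------------
## Three-level Bayesian hierarchical logistic determinant models
##
##   logit P(y=1) = b0 + x'b + u_cluster + v_governorate
##   u ~ N(0, sigma_c^2), v ~ N(0, sigma_g^2)
##
## with weakly informative priors: normal(0, sd 10) on coefficients,
## half-normal(0, sd 2) on the random-effect sds.  Adjusted odds ratios are
## summarized by the posterior median (invariant under reciprocals) with
## 2.5/97.5 percentile credible intervals; the reported variance components
## are the posterior distributions of sigma^2.
## ---------------------------------------------------------------------------

#' Covariate specification helpers
#'
#' Declare a categorical covariate (with an explicit level order, reference
#' level and optional outcome-specific excluded levels whose records are
#' dropped) or a continuous covariate for the determinant models.
#'
#' @param col column name in the record table.
#' @param levels allowed levels in display order (`NULL` = observed order).
#' @param ref reference level (defaults to the first).
#' @param drop levels excluded for this outcome.
#' @return a covariate specification list.
#' @export
cov_factor <- function(col, levels, ref = levels[1], drop = NULL)
  list(col = col, levels = levels, ref = ref, drop = drop, numeric = FALSE)

#' @rdname cov_factor
#' @export
cov_numeric <- function(col) list(col = col, numeric = TRUE)

#' Covariate set for a determinant outcome
#'
#' The per-outcome covariate applicability, reference categories and level
#' sets used by the determinant models.  Service-indicator outcomes use the
#' mother/child covariates; the financial-hardship outcomes (`CATA`,
#' `IMPOV`) use household-head covariates, member counts and the survey-year
#' indicator; wealth quintile is not applicable for impoverishment (the
#' quintile ranking is consumption-based and mechanically tied to that
#' outcome).  Some outcome-specific level exclusions apply (e.g. the top
#' antenatal-care category for oral rehydration therapy).
#'
#' @param outcome one of `"FPNS"`, `"ANC4"`, `"FULL"`, `"ARI"`, `"ORT"`,
#'   `"CATA"`, `"IMPOV"`.
#' @return list of covariate specifications.
#' @export
determinant_covariates <- function(outcome) {
  mother_age <- cov_factor("mother_age", c("<20", "20-35", ">=36"))
  mother_edu <- cov_factor("mother_edu",
                           c("none", "primary", "secondary", "higher"))
  anc <- cov_factor("anc_visits", as.character(0:4))
  anc_ort <- cov_factor("anc_visits", as.character(0:3), drop = "4")
  bo_full <- cov_factor("birth_order", c("0", "1", "2-3", ">=4"))
  wealth <- cov_factor("wealth_quintile", as.character(1:5))
  residence <- cov_factor("residence", c("urban", "rural"))
  child_sex <- cov_factor("child_sex", c("male", "female"))
  head_edu <- cov_factor("head_edu",
                         c("none", "primary", "secondary", "higher", "other"))
  switch(outcome,
    FPNS = list(mother_age, mother_edu,
                cov_factor("birth_order", c("0", "1", "2-3"), drop = ">=4"),
                wealth, residence),
    ANC4 = list(mother_age, mother_edu,
                cov_factor("birth_order", c("1", "2-3", ">=4"), drop = "0"),
                wealth, residence),
    FULL = list(mother_age, mother_edu, anc, bo_full, child_sex, wealth,
                residence),
    ARI = list(mother_age, mother_edu, anc, bo_full, child_sex, wealth,
               residence),
    ORT = list(mother_age, mother_edu, anc_ort, bo_full, child_sex, wealth,
               residence),
    CATA = list(cov_numeric("head_age"),
                cov_factor("head_sex", c("male", "female")), head_edu,
                cov_numeric("n_under5"), cov_numeric("n_over65"), wealth,
                residence, cov_factor("year", NULL)),
    IMPOV = list(cov_numeric("head_age"),
                 cov_factor("head_sex", c("male", "female")), head_edu,
                 cov_numeric("n_under5"), cov_numeric("n_over65"), residence,
                 cov_factor("year", NULL)),
    stop("no covariate set defined for outcome '", outcome, "'",
         call. = FALSE))
}

#' Build the determinant-model design matrix
#'
#' Dummy-codes the categorical covariates against their stated reference
#' levels and appends the continuous covariates; the row-record mapping and
#' the column-to-(covariate, level) maps are retained.  Records in an
#' outcome-excluded level are dropped with a message; an unseen category is
#' an error naming the value.
#'
#' @param records record table.
#' @param covariates list of covariate specifications, e.g. from
#'   [determinant_covariates()].
#' @return list with `X` (model matrix, no intercept column), `keep`
#'   (logical row filter applied to `records`), `map` (data.frame column,
#'   covariate, level, reference).
#' @export
build_design_matrix <- function(records, covariates) {
  keep <- rep(TRUE, nrow(records))
  for (cv in covariates) {
    if (!cv$numeric && !is.null(cv$drop)) {
      bad <- as.character(records[[cv$col]]) %in% cv$drop
      if (any(bad)) {
        message(sum(bad), " record(s) in excluded level(s) of '", cv$col,
                "' dropped")
        keep <- keep & !bad
      }
    }
  }
  rec <- records[keep, , drop = FALSE]
  cols <- list(); map <- list()
  for (cv in covariates) {
    v <- rec[[cv$col]]
    if (is.null(v)) stop("column '", cv$col, "' not found", call. = FALSE)
    if (isTRUE(cv$numeric)) {
      ## centred for sampler conditioning; the per-unit OR is unchanged
      cols[[cv$col]] <- as.numeric(v) - mean(as.numeric(v))
      map[[length(map) + 1L]] <- data.frame(column = cv$col,
                                            covariate = cv$col,
                                            level = NA_character_,
                                            reference = NA_character_)
      next
    }
    v <- as.character(v)
    levels <- cv$levels %||% sort(unique(v))
    ref <- cv$ref %||% levels[1]
    unseen <- setdiff(unique(v), levels)
    if (length(unseen))
      stop("unseen category in '", cv$col, "': ",
           paste(unseen, collapse = ", "), call. = FALSE)
    for (lv in setdiff(levels, ref)) {
      cn <- paste0(cv$col, ":", lv)
      cols[[cn]] <- as.numeric(v == lv)
      map[[length(map) + 1L]] <- data.frame(column = cn, covariate = cv$col,
                                            level = lv, reference = ref)
    }
  }
  X <- do.call(cbind, cols)
  list(X = X, keep = keep, map = do.call(rbind, map))
}

jags_determinant_model <- function(P, weighted) {
  lik <- if (weighted) "
    zeros[i] ~ dpois(phi[i])
    phi[i] <- -w[i] * (y[i] * log(p[i]) + (1 - y[i]) * log(1 - p[i])) + 10" else "
    y[i] ~ dbern(p[i])"
  ## non-centred random effects: avoids the funnel between the group
  ## deviations and their sd when the data are weakly informative per group
  paste0("model {
  for (i in 1:N) {", lik, "
    logit(p[i]) <- b0 + inprod(b[1:P], X[i, 1:P]) + sig_c * zu[cl[i]] +
      sig_g * zv[gov[i]]
  }
  for (j in 1:C) { zu[j] ~ dnorm(0, 1) }
  for (j in 1:G) { zv[j] ~ dnorm(0, 1) }
  b0 ~ dnorm(0, 0.01)
  for (k in 1:P) { b[k] ~ dnorm(0, 0.01) }
  sig_c ~ dnorm(0, 0.25) T(0,)
  sig_g ~ dnorm(0, 0.25) T(0,)
}")
}

#' Fit a three-level hierarchical logistic determinant model
#'
#' Adjusted odds ratios with 95% credible intervals for one binary outcome,
#' with normal random effects for sampling clusters nested in governorates.
#' Service-indicator outcomes are restricted to their eligible denominators;
#' `CATA` / `IMPOV` are first derived from the expenditure columns.  By
#' default the likelihood is unweighted (the multilevel structure carries
#' the design); `weights = "pseudo"` uses a weighted pseudo-likelihood with
#' weights normalized to mean 1.
#'
#' @param records individual or household record table.
#' @param outcome outcome code (see [determinant_covariates()]), or the name
#'   of a 0/1 column in `records` when `covariates` is supplied.
#' @param covariates covariate specification list; defaults to
#'   [determinant_covariates()] for the known outcomes.
#' @param years optional survey-year filter (e.g. the latest wave for
#'   service indicators).
#' @param threshold,poverty_line financial-hardship parameters (used for
#'   `CATA` / `IMPOV`).
#' @param weights `"none"` (default) or `"pseudo"`.
#' @param chains,adapt,burnin,iter,thin MCMC settings.
#' @param rhat_max convergence threshold on split R-hat.
#' @param seed integer seed.
#' @return object of class `uhc_determinants` with the OR table, variance
#'   components, draws and diagnostics.
#' @export
fit_determinants <- function(records, outcome, covariates = NULL,
                             years = NULL, threshold = 0.10,
                             poverty_line = 2.5,
                             weights = c("none", "pseudo"),
                             chains = 2, adapt = 300, burnin = 500,
                             iter = 1000, thin = 1, rhat_max = 1.05,
                             seed = 1L) {
  weights <- match.arg(weights)
  if (!is.null(years)) records <- records[records$year %in% years, ]
  if (outcome == "CATA") {
    records$y_CATA <- as.integer(flag_catastrophic(records, threshold))
    records$elig_CATA <- TRUE
  } else if (outcome == "IMPOV") {
    records$y_IMPOV <- as.integer(flag_impoverishment(records, poverty_line))
    records$elig_IMPOV <- TRUE
  }
  ycol <- paste0("y_", outcome)
  ecol <- paste0("elig_", outcome)
  if (is.null(records[[ycol]])) {
    ycol <- outcome
    if (is.null(records[[ycol]]))
      stop("no outcome column for '", outcome, "'", call. = FALSE)
  }
  elig <- if (!is.null(records[[ecol]])) records[[ecol]] %in% TRUE
          else !is.na(records[[ycol]])
  rec <- records[elig & !is.na(records[[ycol]]), , drop = FALSE]
  if (nrow(rec) < 50)
    stop("outcome defined on fewer than 50 eligible records", call. = FALSE)
  if (is.null(covariates)) covariates <- determinant_covariates(outcome)
  dm <- build_design_matrix(rec, covariates)
  rec <- rec[dm$keep, , drop = FALSE]
  y <- as.integer(rec[[ycol]])
  X <- dm$X
  P <- ncol(X)

  ## separation screen: every covariate level observed in both outcome classes
  sep <- character(0)
  for (k in seq_len(P)) {
    if (all(dm$map$level[k] %in% NA)) next
    tab <- table(factor(X[, k] > 0, c(FALSE, TRUE)), factor(y, 0:1))
    if (any(tab[2, ] == 0)) sep <- c(sep, colnames(X)[k])
  }
  if (length(sep))
    warning("possible separation: level(s) ", paste(sep, collapse = ", "),
            " not observed in both outcome classes", call. = FALSE)

  cl_ids <- sort(unique(rec$cluster))
  gov_ids <- sort(unique(rec$governorate))
  dat <- list(y = y, X = X, cl = match(rec$cluster, cl_ids),
              gov = match(rec$governorate, gov_ids), N = length(y),
              C = length(cl_ids), G = length(gov_ids), P = P)
  if (weights == "pseudo") {
    w <- rec$weight / mean(rec$weight)
    dat$w <- w
    dat$zeros <- rep(0, length(y))
    dat$y <- y
  }
  inits <- lapply(seq_len(chains), function(c)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = fan_seed(seed, paste0("det-chain-", c))))
  jm <- rjags::jags.model(textConnection(
    jags_determinant_model(P, weights == "pseudo")), data = dat,
    inits = inits, n.chains = chains, n.adapt = adapt, quiet = TRUE)
  stats::update(jm, burnin, progress.bar = "none")
  samp <- rjags::coda.samples(jm, c("b0", "b", "sig_c", "sig_g"),
                              n.iter = iter, thin = thin,
                              progress.bar = "none")
  draws <- do.call(rbind, lapply(samp, as.matrix))
  cn <- colnames(draws); cn[cn == "b"] <- "b[1]"; colnames(draws) <- cn
  chain_id <- rep(seq_len(chains), each = nrow(samp[[1]]))

  ## deviance (unweighted Bernoulli) in blocks, for DIC
  bcols <- sprintf("b[%d]", seq_len(P))
  nd <- nrow(draws)
  dev_draws <- numeric(nd)
  ## random effects are not monitored; the deviance trace marginalizes the
  ## linear predictor to its fixed part plus posterior-mean group effects
  ## being unavailable, so DIC here compares fixed-effect structures
  eta_fix <- function(idx) {
    draws[idx, "b0"] + draws[idx, bcols, drop = FALSE] %*% t(X)
  }
  for (start in seq(1, nd, by = 250)) {
    idx <- start:min(start + 249, nd)
    Pm <- pmin(pmax(invlogit(eta_fix(idx)), 1e-12), 1 - 1e-12)
    Ym <- matrix(y, length(idx), length(y), byrow = TRUE)
    dev_draws[idx] <- -2 * rowSums(Ym * log(Pm) + (1 - Ym) * log1p(-Pm))
  }
  pm <- colMeans(draws)
  eta_pm <- pm["b0"] + drop(X %*% pm[bcols])
  dev_at_mean <- -2 * sum(stats::dbinom(y, 1, invlogit(eta_pm), log = TRUE))

  diag_df <- data.frame(parameter = colnames(draws))
  diag_df$rhat <- vapply(colnames(draws), function(p)
    split_rhat(matrix(draws[, p], ncol = chains)), numeric(1))
  ess <- try(coda::effectiveSize(samp), silent = TRUE)
  diag_df$ess <- if (inherits(ess, "try-error")) NA_real_
                 else as.numeric(ess[diag_df$parameter])
  converged <- all(diag_df$rhat <= rhat_max, na.rm = TRUE)
  if (!converged)
    warning("determinant fit for ", outcome, " did not converge (max split ",
            "R-hat ", sprintf("%.3f", max(diag_df$rhat, na.rm = TRUE)), ")",
            call. = FALSE)

  or_table <- or_table_from_draws(draws, dm$map, P)
  vc <- rbind(
    varcomp_row("cluster", draws[, "sig_c"]),
    varcomp_row("governorate", draws[, "sig_g"]))

  structure(list(outcome = outcome, or_table = or_table, varcomp = vc,
                 draws = draws, chain = chain_id, chains = chains,
                 map = dm$map, n = length(y), n_clusters = dat$C,
                 n_governorates = dat$G, separation = sep,
                 deviance = dev_draws, deviance_at_mean = dev_at_mean,
                 diagnostics = diag_df, converged = converged,
                 weights = weights, seed = seed,
                 mcmc = list(chains = chains, adapt = adapt, burnin = burnin,
                             iter = iter, thin = thin),
                 call = match.call()),
            class = "uhc_determinants")
}

varcomp_row <- function(label, sig_draws) {
  v <- sig_draws^2
  q <- stats::quantile(v, c(0.5, ci_probs))
  data.frame(component = label, variance = q[1], lo = q[2], hi = q[3],
             row.names = NULL)
}

or_table_from_draws <- function(draws, map, P) {
  rows <- list()
  for (cvr in unique(map$covariate)) {
    sub <- map[map$covariate == cvr, ]
    if (!all(is.na(sub$level))) {
      ref <- sub$reference[1]
      rows[[length(rows) + 1L]] <- data.frame(
        covariate = cvr, level = ref, or = 1, lo = NA_real_, hi = NA_real_,
        reference = TRUE)
    }
    for (i in seq_len(nrow(sub))) {
      k <- match(sub$column[i], map$column)
      od <- exp(draws[, sprintf("b[%d]", k)])
      q <- stats::quantile(od, c(0.5, ci_probs))
      rows[[length(rows) + 1L]] <- data.frame(
        covariate = cvr, level = sub$level[i] %||% NA_character_,
        or = q[1], lo = q[2], hi = q[3], reference = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Swap the reference level of a binary covariate
#'
#' Reference-level swapping is an exact reparameterisation of the logistic
#' model, so it is applied draw-wise to the stored posterior: the
#' covariate's coefficient draws are negated (OR_new = 1/OR_old for every
#' draw) and the intercept absorbs the shift.
#'
#' @param fit a `uhc_determinants` object.
#' @param covariate name of a two-level covariate in the fit.
#' @return the modified `uhc_determinants` object.
#' @export
swap_reference <- function(fit, covariate) {
  sub <- fit$map[fit$map$covariate == covariate & !is.na(fit$map$level), ]
  if (nrow(sub) != 1)
    stop("'", covariate, "' is not a binary covariate in this fit",
         call. = FALSE)
  k <- match(sub$column, fit$map$column)
  col <- sprintf("b[%d]", k)
  fit$draws[, "b0"] <- fit$draws[, "b0"] + fit$draws[, col]
  fit$draws[, col] <- -fit$draws[, col]
  fit$map$reference[fit$map$column == sub$column] <- sub$level
  fit$map$level[fit$map$column == sub$column] <- sub$reference
  fit$or_table <- or_table_from_draws(fit$draws, fit$map,
                                      sum(!is.na(fit$map$column)))
  fit
}

#' @export
print.uhc_determinants <- function(x, digits = 2, ...) {
  cat(sprintf("Hierarchical determinants of %s (n = %d, %d clusters, %d governorates)\n",
              x$outcome, x$n, x$n_clusters, x$n_governorates))
  cat(sprintf("  converged: %s (max split R-hat %.3f)\n",
              ifelse(x$converged, "yes", "NO"),
              max(x$diagnostics$rhat, na.rm = TRUE)))
  tb <- x$or_table
  tb$or <- round(tb$or, digits); tb$lo <- round(tb$lo, digits)
  tb$hi <- round(tb$hi, digits)
  print(tb, row.names = FALSE)
  cat("Variance components:\n")
  vc <- x$varcomp
  vc[, -1] <- round(vc[, -1], digits)
  print(vc, row.names = FALSE)
  invisible(x)
}

#' @export
coef.uhc_determinants <- function(object, ...) {
  apply(object$draws, 2, stats::median)
}

#' @export
summary.uhc_determinants <- function(object, ...) {
  print(object)
  invisible(object$or_table)
}
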