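## ---------------------------------------------------------------------------
## Synthetic household-survey generator
##
## Emulates the two survey families the monitoring pipeline consumes:
##  * MICS-like woman/child records with service-indicator outcomes, observed
##    in repeated cross-sectional waves under multi-stage cluster sampling;
##  * HSES-like household records with consumption, food consumption and
##    out-of-pocket (OOP) health spending.
## Every random quantity flows from config$seed, and the realized generating
## parameters are attached as a "ground_truth" attribute so downstream
## estimators can be tested for parameter recovery.
## ---------------------------------------------------------------------------

#' Canonical service-indicator parameter table
#'
#' One row per indicator with the logit-scale generating parameters:
#' `intercept` (poorest-extreme, urban, year 2000), `slope` (logit per
#' decade), `wealth_gradient` (logit difference between the extremes of the
#' wealth rank) and `residence_gap` (logit shift for rural residence,
#' negative = rural disadvantage).  `FULL` (full immunisation) is derived as
#' BCG & DTP3 & MSL received, so it carries no generating parameters of its
#' own.  The 14th slot (`EXTRA`) is user-configurable and defaults to an
#' ANC1-like structure.
#'
#' @return data.frame with columns `indicator`, `intercept`, `slope`,
#'   `wealth_gradient`, `residence_gap`, `derived`.
#' @export
default_indicator_params <- function() {
  p <- rbind(
    c("FPNS",  -0.8, 0.3, 0.6, -0.1),
    c("ANC1",   0.5, 0.5, 1.0, -0.5),
    c("ANC4",  -1.2, 0.6, 0.9, -0.6),
    c("INSD",   0.6, 1.0, 0.7, -0.4),
    c("SBA",    1.0, 0.9, 0.5, -0.3),
    c("BCG",    1.2, 0.6, 0.6, -0.3),
    c("DTP3",   0.2, 0.4, 1.2, -0.6),
    c("MSL",    0.4, 0.4, 1.1, -0.5),
    c("FULL",    NA,  NA,  NA,   NA),
    c("ARI",   -0.3, 0.3, 0.5, -0.3),
    c("ORT",   -0.4, 0.2, 0.4, -0.2),
    c("WATER",  1.5, 0.5, 0.8, -0.8),
    c("SAN",    1.3, 0.6, 0.9, -0.9),
    c("EXTRA",  0.5, 0.5, 1.0, -0.5)
  )
  out <- data.frame(
    indicator = p[, 1],
    intercept = as.numeric(p[, 2]),
    slope = as.numeric(p[, 3]),
    wealth_gradient = as.numeric(p[, 4]),
    residence_gap = as.numeric(p[, 5]),
    stringsAsFactors = FALSE
  )
  out$derived <- out$indicator == "FULL"
  out
}

#' Names of the service indicators
#' @return character vector of the 14 indicator codes.
#' @export
uhc_indicators <- function() default_indicator_params()$indicator

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-survey generator.  The defaults
#' emulate the study setting: 18 governorates with an urban/rural split,
#' four MICS-like waves (2000/2006/2011/2018), two HSES-like waves
#' (2007/2012), multi-stage cluster sampling with exact inverse-probability
#' weights, a latent wealth index inducing quintile gradients, logit-linear
#' time trends per indicator, and a zero-inflated logit-normal OOP share of
#' household consumption producing realistic catastrophic-payment incidence
#' (about 2-3% in the first HSES wave rising to 10-12% in the second).
#'
#' @param n_governorates number of governorates (default 18).
#' @param years MICS-like survey years.
#' @param hses_years HSES-like survey years.
#' @param clusters_per_stratum sampled clusters per governorate-residence
#'   stratum per wave.
#' @param households_per_cluster sampled households per cluster.
#' @param indicator_params per-indicator logit-scale parameter table, see
#'   [default_indicator_params()].
#' @param predictor_effects named logit-scale coefficients (per standard
#'   deviation of the predictor) for `idp`, `density`, `hexp` entering the
#'   coverage linear predictor.
#' @param covariate_effects optional named logit-scale effects of individual
#'   covariates, names of the form `"mother_edu:higher"`; applied to all
#'   indicators (default none).
#' @param re_sd named sds of the normal cluster and governorate random
#'   effects on the logit scale.
#' @param oop_model list with `mu`, `sd` (logit-scale location/spread of the
#'   positive OOP share of consumption), `p_zero` (point mass of
#'   zero-spenders), `year_effect` (logit shift for the later HSES wave) and
#'   `wealth_tilt` (logit shift per unit of the latent wealth index; positive
#'   = richer households devote a larger share to health).
#' @param poverty_line poverty line in currency per person per day.
#' @param predictor_model list controlling the predictor series:
#'   `observed_years`, `idp_spike_year`, `idp_spike_mult`, `density_growth`,
#'   `hexp_growth`.
#' @param seed master integer seed; fixes the full output byte-for-byte.
#' @return an object of class `uhc_sim_config`.
#' @export
sim_config <- function(n_governorates = 18,
                       years = c(2000, 2006, 2011, 2018),
                       hses_years = c(2007, 2012),
                       clusters_per_stratum = 6,
                       households_per_cluster = 10,
                       indicator_params = default_indicator_params(),
                       predictor_effects = c(idp = -0.15, density = 0.05,
                                             hexp = 0.2),
                       covariate_effects = NULL,
                       re_sd = c(cluster = 0.3, governorate = 0.2),
                       oop_model = list(mu = -4.6, sd = 1.3, p_zero = 0.25,
                                        year_effect = 1.0, wealth_tilt = 0.4),
                       poverty_line = 2.5,
                       predictor_model = list(observed_years = 2000:2018,
                                              idp_spike_year = 2014,
                                              idp_spike_mult = 3,
                                              density_growth = 0.025,
                                              hexp_growth = 0.08),
                       seed = 1L) {
  stopifnot(n_governorates >= 1, clusters_per_stratum >= 1,
            households_per_cluster >= 1, length(years) >= 1,
            length(hses_years) >= 1)
  if (any(c(n_governorates, clusters_per_stratum,
            households_per_cluster) %% 1 != 0))
    stop("counts must be whole numbers", call. = FALSE)
  req <- c("indicator", "intercept", "slope", "wealth_gradient",
           "residence_gap")
  if (!all(req %in% names(indicator_params)))
    stop("indicator_params must have columns ",
         paste(req, collapse = ", "), call. = FALSE)
  if (is.null(indicator_params$derived))
    indicator_params$derived <- indicator_params$indicator == "FULL"
  act <- indicator_params[!indicator_params$derived, ]
  if (!all(is.finite(act$wealth_gradient)))
    stop("wealth gradients must be finite", call. = FALSE)
  stopifnot(all(c("cluster", "governorate") %in% names(re_sd)),
            all(re_sd >= 0))
  om <- utils::modifyList(
    list(mu = -4.6, sd = 1.3, p_zero = 0.25, year_effect = 1.0,
         wealth_tilt = 0.4), as.list(oop_model))
  if (om$p_zero < 0 || om$p_zero > 1 || om$sd < 0)
    stop("invalid oop_model", call. = FALSE)
  pm <- utils::modifyList(
    list(observed_years = 2000:2018, idp_spike_year = 2014,
         idp_spike_mult = 3, density_growth = 0.025, hexp_growth = 0.08),
    as.list(predictor_model))
  stopifnot(poverty_line > 0)
  cfg <- list(n_governorates = as.integer(n_governorates),
              years = sort(as.integer(years)),
              hses_years = sort(as.integer(hses_years)),
              clusters_per_stratum = as.integer(clusters_per_stratum),
              households_per_cluster = as.integer(households_per_cluster),
              indicator_params = indicator_params,
              predictor_effects = predictor_effects,
              covariate_effects = covariate_effects,
              re_sd = re_sd, oop_model = om, poverty_line = poverty_line,
              predictor_model = pm, seed = as.integer(seed))
  class(cfg) <- "uhc_sim_config"
  cfg
}

#' @export
print.uhc_sim_config <- function(x, ...) {
  cat("Synthetic survey configuration\n")
  cat(sprintf("  %d governorates x urban/rural, %d clusters/stratum, %d hh/cluster\n",
              x$n_governorates, x$clusters_per_stratum,
              x$households_per_cluster))
  cat("  MICS-like waves:", paste(x$years, collapse = ", "), "\n")
  cat("  HSES-like waves:", paste(x$hses_years, collapse = ", "), "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

## draw the two-stage sample for one wave: strata are governorate x residence,
## first-stage units are clusters drawn from a finite frame, second stage
## households; weights are exact inverse selection probabilities
draw_design <- function(cfg, year, id_offset = 0L) {
  gov <- seq_len(cfg$n_governorates)
  strata <- expand.grid(governorate = gov,
                        residence = c("urban", "rural"),
                        stringsAsFactors = FALSE)
  out <- vector("list", nrow(strata))
  next_cluster <- id_offset
  for (s in seq_len(nrow(strata))) {
    frame_clusters <- cfg$clusters_per_stratum * sample(3:8, 1)
    cl_frames <- cfg$households_per_cluster * sample(3:6,
                                                     cfg$clusters_per_stratum,
                                                     replace = TRUE)
    p1 <- cfg$clusters_per_stratum / frame_clusters
    rows <- lapply(seq_len(cfg$clusters_per_stratum), function(k) {
      p2 <- cfg$households_per_cluster / cl_frames[k]
      data.frame(year = year,
                 governorate = strata$governorate[s],
                 residence = strata$residence[s],
                 cluster = next_cluster + k,
                 weight = 1 / (p1 * p2),
                 n = cfg$households_per_cluster)
    })
    next_cluster <- next_cluster + cfg$clusters_per_stratum
    out[[s]] <- do.call(rbind, rows)
  }
  do.call(rbind, out)
}

## latent wealth index: urban and richer governorates shifted up; the ridit
## (weighted population rank in [0,1]) is computed empirically within wave
draw_wealth <- function(df, gov_wealth) {
  mu <- ifelse(df$residence == "urban", 0.4, -0.4) + gov_wealth[df$governorate]
  windex <- stats::rnorm(nrow(df), mu, 1)
  windex
}

weighted_ridit <- function(index, w) {
  o <- order(index, seq_along(index))   # stable tie-break by record order
  cw <- cumsum(w[o])
  W <- cw[length(cw)]
  r <- numeric(length(index))
  r[o] <- (cw - w[o] / 2) / W
  r
}

## mother covariates, socially patterned on the wealth index
draw_mother_covariates <- function(n, windex) {
  edu_star <- 0.8 * windex + stats::rnorm(n)
  mother_edu <- cut(edu_star, c(-Inf, -0.5, 0.5, 1.5, Inf),
                    labels = c("none", "primary", "secondary", "higher"))
  mother_age <- sample(c("<20", "20-35", ">=36"), n, replace = TRUE,
                       prob = c(0.15, 0.65, 0.20))
  anc_star <- 0.5 * windex + 0.3 * (as.integer(mother_edu) - 1) +
    stats::rnorm(n)
  anc_visits <- as.integer(cut(anc_star, c(-Inf, -0.8, 0, 0.7, 1.4, Inf))) - 1L
  birth_order <- sample(c("0", "1", "2-3", ">=4"), n, replace = TRUE,
                        prob = c(0.10, 0.25, 0.35, 0.30))
  child_sex <- sample(c("male", "female"), n, replace = TRUE)
  data.frame(mother_age = mother_age,
             mother_edu = as.character(mother_edu),
             anc_visits = anc_visits,
             birth_order = birth_order,
             child_sex = child_sex,
             stringsAsFactors = FALSE)
}

covariate_effect_vector <- function(effects, df) {
  eta <- numeric(nrow(df))
  if (is.null(effects)) return(eta)
  for (nm in names(effects)) {
    parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2 || is.null(df[[parts[1]]]))
      stop("covariate_effects names must be '<column>:<level>'", call. = FALSE)
    eta <- eta + effects[[nm]] * (as.character(df[[parts[1]]]) == parts[2])
  }
  eta
}

## standardized predictor values per (governorate, year); national series are
## broadcast to all governorates
predictor_z <- function(pred, cfg) {
  vars <- unique(pred$variable)
  z <- list()
  for (v in vars) {
    sub <- pred[pred$variable == v & pred$observed, ]
    mu <- mean(sub$value); sdv <- stats::sd(sub$value)
    if (!is.finite(sdv) || sdv == 0) sdv <- 1
    sub$z <- (sub$value - mu) / sdv
    z[[v]] <- sub
  }
  lookup <- function(v, gov, year) {
    s <- z[[v]]
    if (all(is.na(s$governorate))) {
      s$z[match(year, s$year)]
    } else {
      s$z[match(paste(gov, year), paste(s$governorate, s$year))]
    }
  }
  out <- expand.grid(governorate = seq_len(cfg$n_governorates),
                     year = sort(unique(pred$year[pred$observed])))
  for (v in vars) out[[v]] <- lookup(v, out$governorate, out$year)
  out
}

check_regime <- function(cfg) {
  act <- cfg$indicator_params[!cfg$indicator_params$derived, ]
  tt <- (cfg$years - 2000) / 10
  for (i in seq_len(nrow(act))) {
    eta <- outer(act$intercept[i] + act$slope[i] * tt,
                 c(0, act$wealth_gradient[i]), "+")
    eta <- c(eta, eta + act$residence_gap[i])
    p <- invlogit(eta)
    if (any(p < 0.001 | p > 0.999))
      stop(sprintf(paste0("indicator '%s': expected coverage outside ",
                          "(0.001, 0.999); unusable simulation regime"),
                   act$indicator[i]), call. = FALSE)
  }
  invisible(TRUE)
}

#' Simulate MICS-like woman/child survey records
#'
#' One record per eligible woman with a recent birth, per wave.  Outcomes are
#' Bernoulli draws from a logit-linear model: intercept + time trend (per
#' decade since 2000) + wealth gradient times the weighted wealth rank
#' (ridit) + rural residence gap + standardized governorate-level predictor
#' terms + normal cluster and governorate random effects.  Full immunisation
#' is derived as BCG & DTP3 & MSL all received.  Weights are exact inverse
#' selection probabilities of the two-stage design.
#'
#' @param config a [sim_config()] object.
#' @return data.frame of individual records with design columns
#'   (`governorate`, `residence`, `cluster`, `weight`), wealth index and
#'   quintile, mother covariates, and per-indicator eligibility
#'   (`elig_<IND>`) and outcome (`y_<IND>`) columns.  The realized generating
#'   parameters are attached as `attr(, "ground_truth")`.
#' @export
simulate_mics <- function(config) {
  stopifnot(inherits(config, "uhc_sim_config"))
  check_regime(config)
  cfg <- config
  set.seed(fan_seed(cfg$seed, "mics"))
  pred <- simulate_predictors(cfg)
  pz <- predictor_z(pred, cfg)

  gov_wealth <- stats::rnorm(cfg$n_governorates, 0, 0.3)
  act <- cfg$indicator_params[!cfg$indicator_params$derived, ]
  gov_eff <- matrix(stats::rnorm(cfg$n_governorates * nrow(act), 0,
                                 cfg$re_sd[["governorate"]]),
                    cfg$n_governorates, nrow(act),
                    dimnames = list(NULL, act$indicator))

  waves <- vector("list", length(cfg$years))
  offset <- 0L
  for (w in seq_along(cfg$years)) {
    yr <- cfg$years[w]
    des <- draw_design(cfg, yr, offset)
    offset <- max(des$cluster)
    df <- des[rep(seq_len(nrow(des)), des$n),
              c("year", "governorate", "residence", "cluster", "weight")]
    rownames(df) <- NULL
    n <- nrow(df)
    df$windex <- draw_wealth(df, gov_wealth)
    df$ridit <- weighted_ridit(df$windex, df$weight)
    df$wealth_quintile <- assign_wealth_quintiles(df$windex, df$weight)
    df <- cbind(df, draw_mother_covariates(n, df$windex))

    cl_ids <- sort(unique(df$cluster))
    cl_eff <- matrix(stats::rnorm(length(cl_ids) * nrow(act), 0,
                                  cfg$re_sd[["cluster"]]),
                     length(cl_ids), nrow(act),
                     dimnames = list(NULL, act$indicator))
    cl_row <- match(df$cluster, cl_ids)
    tdec <- (yr - 2000) / 10
    rural <- as.numeric(df$residence == "rural")
    cov_eta <- covariate_effect_vector(cfg$covariate_effects, df)
    pz_row <- match(paste(df$governorate, yr), paste(pz$governorate, pz$year))
    pred_eta <- numeric(n)
    for (v in names(cfg$predictor_effects)) {
      if (!is.null(pz[[v]]))
        pred_eta <- pred_eta + cfg$predictor_effects[[v]] * pz[[v]][pz_row]
    }

    elig_p <- c(FPNS = 1, ANC1 = 1, ANC4 = 1, INSD = 1, SBA = 1, BCG = 0.9,
                DTP3 = 0.9, MSL = 0.9, ARI = 0.15, ORT = 0.15, WATER = 1,
                SAN = 1, EXTRA = 1)
    for (i in seq_len(nrow(act))) {
      ind <- act$indicator[i]
      ep <- if (ind %in% names(elig_p)) elig_p[[ind]] else 1
      elig <- stats::rbinom(n, 1, ep) == 1
      eta <- act$intercept[i] + act$slope[i] * tdec +
        act$wealth_gradient[i] * df$ridit +
        act$residence_gap[i] * rural +
        pred_eta + cov_eta +
        gov_eff[df$governorate, ind] + cl_eff[cl_row, ind]
      y <- ifelse(elig, stats::rbinom(n, 1, invlogit(eta)), NA_integer_)
      df[[paste0("elig_", ind)]] <- elig
      df[[paste0("y_", ind)]] <- y
    }
    ## full immunisation: all three vaccine doses received, on the shared
    ## child-immunisation denominator
    if (any(cfg$indicator_params$derived) &&
        all(c("BCG", "DTP3", "MSL") %in% act$indicator)) {
      df$elig_FULL <- df$elig_BCG & df$elig_DTP3 & df$elig_MSL
      df$y_FULL <- ifelse(df$elig_FULL,
                          as.integer(df$y_BCG == 1 & df$y_DTP3 == 1 &
                                       df$y_MSL == 1),
                          NA_integer_)
    }
    waves[[w]] <- df
  }
  out <- do.call(rbind, waves)
  out$record_id <- seq_len(nrow(out))
  out <- out[, c("record_id", setdiff(names(out), "record_id"))]
  attr(out, "ground_truth") <- list(
    indicator_params = cfg$indicator_params,
    predictor_effects = cfg$predictor_effects,
    covariate_effects = cfg$covariate_effects,
    re_sd = cfg$re_sd,
    gov_wealth = gov_wealth,
    gov_effects = gov_eff,
    predictors = pred,
    seed = cfg$seed)
  out
}

#' Simulate HSES-like household expenditure records
#'
#' Per-household total consumption (per month), food consumption,
#' out-of-pocket (OOP) health spending, head covariates and member counts.
#' The OOP share of consumption follows a zero-inflated logit-normal model
#' (default 25% zero-spenders) with a wave effect and a wealth tilt, which
#' reproduces the right-skewed, zero-inflated OOP distributions real
#' expenditure surveys show; OOP never exceeds total consumption by
#' construction.
#'
#' @param config a [sim_config()] object.
#' @return data.frame of household records with the design columns, head
#'   covariates, member counts, `consumption`, `food_consumption`, `oop`
#'   (all currency per household per month) and `hh_size`; ground truth in
#'   `attr(, "ground_truth")`.
#' @export
simulate_hses <- function(config) {
  stopifnot(inherits(config, "uhc_sim_config"))
  cfg <- config
  om <- cfg$oop_model
  set.seed(fan_seed(cfg$seed, "hses"))
  gov_wealth <- stats::rnorm(cfg$n_governorates, 0, 0.3)

  waves <- vector("list", length(cfg$hses_years))
  offset <- 0L
  for (w in seq_along(cfg$hses_years)) {
    yr <- cfg$hses_years[w]
    des <- draw_design(cfg, yr, offset)
    offset <- max(des$cluster)
    df <- des[rep(seq_len(nrow(des)), des$n),
              c("year", "governorate", "residence", "cluster", "weight")]
    rownames(df) <- NULL
    n <- nrow(df)
    df$windex <- draw_wealth(df, gov_wealth)
    df$wealth_quintile <- assign_wealth_quintiles(df$windex, df$weight)

    df$head_age <- round(pmin(pmax(stats::rnorm(n, 45, 12), 18), 90))
    df$head_sex <- sample(c("male", "female"), n, TRUE, prob = c(0.88, 0.12))
    edu_star <- 0.7 * df$windex + stats::rnorm(n)
    df$head_edu <- as.character(cut(edu_star, c(-Inf, -0.4, 0.6, 1.5, Inf),
                                    labels = c("none", "primary",
                                               "secondary", "higher")))
    df$head_edu[stats::runif(n) < 0.03] <- "other"
    df$n_under5 <- stats::rpois(n, 1.0)
    df$n_over65 <- stats::rpois(n, 0.25)
    df$hh_size <- 2L + df$n_under5 + df$n_over65 + stats::rpois(n, 2.5)

    percap <- exp(log(110) + 0.45 * df$windex + stats::rnorm(n, 0, 0.35))
    df$consumption <- percap * df$hh_size
    food_share <- invlogit(stats::rnorm(n, 0.2 - 0.2 * df$windex, 0.3))
    df$food_consumption <- food_share * df$consumption

    late <- as.numeric(yr == max(cfg$hses_years))
    zero <- stats::runif(n) < om$p_zero
    ## cluster- and governorate-level variation in the propensity to spend
    ## on health (access, prices), on the same scale as the MICS generator
    cl_ids <- sort(unique(df$cluster))
    cl_eff <- stats::rnorm(length(cl_ids), 0, cfg$re_sd[["cluster"]])
    gov_eff_y <- stats::rnorm(cfg$n_governorates, 0,
                              cfg$re_sd[["governorate"]])
    share <- invlogit(stats::rnorm(n, om$mu + om$year_effect * late +
                                     om$wealth_tilt * df$windex +
                                     cl_eff[match(df$cluster, cl_ids)] +
                                     gov_eff_y[df$governorate], om$sd))
    share[zero] <- 0
    if (om$sd == 0 && om$p_zero == 1) share[] <- 0
    df$oop <- share * df$consumption
    waves[[w]] <- df
  }
  out <- do.call(rbind, waves)
  out$record_id <- seq_len(nrow(out))
  out <- out[, c("record_id", setdiff(names(out), "record_id"))]
  attr(out, "ground_truth") <- list(
    oop_model = om, poverty_line = cfg$poverty_line,
    gov_wealth = gov_wealth, seed = cfg$seed)
  out
}

#' Simulate governorate-level predictor series
#'
#' Three exogenous predictor series over the observed span (default
#' 2000-2018): internally-displaced-person (IDP) counts per governorate
#' (near-baseline before the configured displacement spike year, default
#' 2014, then a decaying spike), population density per governorate
#' (compound growth), and national health expenditure per capita (compound
#' growth with noise).  All values are nonnegative and deterministic given
#' the seed.
#'
#' @param config a [sim_config()] object.
#' @return long data.frame with columns `variable` (`idp`, `density`,
#'   `hexp`), `governorate` (`NA` for the national series), `year`, `value`,
#'   `observed` (all `TRUE` here; projections set it `FALSE`).
#' @export
simulate_predictors <- function(config) {
  stopifnot(inherits(config, "uhc_sim_config"))
  cfg <- config
  pm <- cfg$predictor_model
  yrs <- pm$observed_years
  if (length(yrs) < 2) stop("need at least 2 predictor years", call. = FALSE)
  set.seed(fan_seed(cfg$seed, "predictors"))
  G <- cfg$n_governorates
  idp_base <- exp(stats::rnorm(G, log(5000), 0.8))
  spike_mag <- pm$idp_spike_mult * exp(stats::rnorm(G, 0, 0.7))
  dens0 <- exp(stats::rnorm(G, log(150), 1))
  hexp0 <- 30 * exp(stats::rnorm(1, 0, 0.1))
  hexp_noise <- stats::rnorm(length(yrs), 0, 0.05)

  rows <- list()
  for (g in seq_len(G)) {
    idp <- idp_base[g] *
      ifelse(yrs >= pm$idp_spike_year,
             1 + spike_mag[g] * exp(-(yrs - pm$idp_spike_year) / 2), 1)
    dens <- dens0[g] * (1 + pm$density_growth)^(yrs - min(yrs))
    rows[[length(rows) + 1L]] <-
      data.frame(variable = "idp", governorate = g, year = yrs, value = idp)
    rows[[length(rows) + 1L]] <-
      data.frame(variable = "density", governorate = g, year = yrs,
                 value = dens)
  }
  rows[[length(rows) + 1L]] <-
    data.frame(variable = "hexp", governorate = NA_integer_, year = yrs,
               value = hexp0 * (1 + pm$hexp_growth)^(yrs - min(yrs)) *
                 exp(hexp_noise))
  out <- do.call(rbind, rows)
  out$observed <- TRUE
  rownames(out) <- NULL
  out
}

#' Simulate a three-level binary-outcome dataset
#'
#' Generic generator for validating hierarchical logistic models: a Bernoulli
#' outcome with one binary exposure of known odds ratio and normal random
#' effects for clusters nested in governorates.
#'
#' @param n number of individuals.
#' @param or true odds ratio of the exposure.
#' @param sigma_cluster,sigma_governorate random-effect sds (logit scale).
#' @param n_clusters,n_governorates numbers of grouping units.
#' @param p0 baseline outcome probability at exposure 0 (median unit).
#' @param year_or optional odds ratio for a two-wave `year` covariate; when
#'   given, records are split evenly across two waves.
#' @param seed integer seed.
#' @return data.frame with `y`, `x`, `cluster`, `governorate` (and `year`
#'   when `year_or` is given); truth in `attr(, "ground_truth")`.
#' @export
simulate_hierarchical_binary <- function(n = 5000, or = 2.0,
                                         sigma_cluster = 0.5,
                                         sigma_governorate = 0.25,
                                         n_clusters = 250,
                                         n_governorates = 18,
                                         p0 = 0.35, year_or = NULL,
                                         seed = 1L) {
  set.seed(fan_seed(seed, "hier-binary"))
  cl2gov <- sample(seq_len(n_governorates), n_clusters, replace = TRUE)
  cluster <- sample(seq_len(n_clusters), n, replace = TRUE)
  governorate <- cl2gov[cluster]
  x <- stats::rbinom(n, 1, 0.5)
  u <- stats::rnorm(n_clusters, 0, sigma_cluster)
  v <- stats::rnorm(n_governorates, 0, sigma_governorate)
  eta <- logit(p0) + log(or) * x + u[cluster] + v[governorate]
  df <- data.frame(x = x, cluster = cluster, governorate = governorate)
  if (!is.null(year_or)) {
    df$year <- rep(c(0L, 1L), length.out = n)
    eta <- eta + log(year_or) * df$year
  }
  df$y <- stats::rbinom(n, 1, invlogit(eta))
  attr(df, "ground_truth") <- list(or = or, year_or = year_or,
                                   sigma_cluster = sigma_cluster,
                                   sigma_governorate = sigma_governorate,
                                   p0 = p0, seed = seed)
  df
}
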