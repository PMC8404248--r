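test_that("a fixed seed reproduces every generated table byte-for-byte", {
  cfg <- small_config(seed = 11)
  expect_identical(simulate_mics(cfg), simulate_mics(cfg))
  expect_identical(simulate_hses(cfg), simulate_hses(cfg))
  expect_identical(simulate_predictors(cfg), simulate_predictors(cfg))
  cfg2 <- small_config(seed = 12)
  expect_false(identical(simulate_mics(cfg)$windex, simulate_mics(cfg2)$windex))
})

test_that("null generator (all effects zero) gives 50% national coverage", {
  cfg <- sim_config(n_governorates = 8, clusters_per_stratum = 6,
                    households_per_cluster = 10, years = 2018,
                    indicator_params = one_indicator(),
                    predictor_effects = no_pred, re_sd = no_noise, seed = 3)
  m <- simulate_mics(cfg)
  est <- estimate_coverage(m, "ANC1", levels = "national")
  expect_equal(est$p, 0.5, tolerance = 3 * est$se / 0.5)
})

test_that("weighted coverage change across waves matches the generating inverse-logit", {
  cfg <- sim_config(n_governorates = 8, clusters_per_stratum = 6,
                    households_per_cluster = 12, years = c(2000, 2018),
                    indicator_params = one_indicator(intercept = -0.2,
                                                     slope = 0.5),
                    predictor_effects = no_pred, re_sd = no_noise, seed = 5)
  m <- simulate_mics(cfg)
  est <- estimate_coverage(m, "ANC1", levels = "national")
  truth <- plogis(-0.2 + 0.5 * (c(2000, 2018) - 2000) / 10)
  for (i in 1:2)
    expect_lt(abs(est$p[i] - truth[i]), 3 * est$se[i] + 1e-9)
  diff_hat <- est$p[est$year == 2018] - est$p[est$year == 2000]
  expect_lt(abs(diff_hat - (truth[2] - truth[1])),
            3 * sqrt(sum(est$se^2)))
})

test_that("unusable simulation regimes are rejected", {
  cfg <- small_config(indicator_params = one_indicator(intercept = 10))
  expect_error(simulate_mics(cfg), "outside")
  expect_error(sim_config(n_governorates = 0), "positive|>= 1")
  expect_error(sim_config(oop_model = list(p_zero = 2)), "oop_model")
})

test_that("weighted quintile shares are a fifth of the population each", {
  cfg <- small_config(seed = 21)
  m <- simulate_mics(cfg)
  for (yr in unique(m$year)) {
    sub <- m[m$year == yr, ]
    sh <- tapply(sub$weight, sub$wealth_quintile, sum) / sum(sub$weight)
    expect_equal(length(sh), 5L)
    # each share within one (largest) household weight of 20%
    tol <- max(sub$weight) / sum(sub$weight)
    expect_true(all(abs(sh - 0.2) <= tol))
  }
})

test_that("household expenditure respects its accounting identities", {
  h <- simulate_hses(small_config(seed = 8))
  expect_true(all(h$oop <= h$consumption))
  expect_true(all(h$oop >= 0))
  expect_true(all(h$food_consumption < h$consumption))
  expect_true(all(h$weight > 0))
  expect_true(all(h$hh_size >= 2))
})

test_that("an all-zero OOP regime produces zero catastrophic incidence", {
  cfg <- small_config(oop_model = list(mu = -4, sd = 1, p_zero = 1), seed = 2)
  h <- simulate_hses(cfg)
  expect_true(all(h$oop == 0))
  fp <- financial_protection(h, poverty_line = cfg$poverty_line)
  nat <- fp$incidence[fp$incidence$level == "national", ]
  expect_true(all(nat$p == 0))
})

test_that("catastrophic incidence matches the logit-normal tail oracle", {
  # no wealth tilt, no cluster/governorate variation, no wave effect:
  # P(share > t) = (1 - p_zero) * (1 - pnorm((logit(t) - mu)/sd)) exactly
  om <- list(mu = -3.2, sd = 1.1, p_zero = 0.25, year_effect = 0,
             wealth_tilt = 0)
  cfg <- sim_config(n_governorates = 8, clusters_per_stratum = 8,
                    households_per_cluster = 12, hses_years = 2012,
                    oop_model = om, re_sd = no_noise, seed = 13)
  h <- simulate_hses(cfg)
  fp <- financial_protection(h, threshold = 0.10)
  nat <- fp$incidence[fp$incidence$level == "national" &
                        fp$incidence$indicator == "CATA", ]
  tail_truth <- (1 - om$p_zero) *
    (1 - pnorm((qlogis(0.10) - om$mu) / om$sd))
  expect_lt(abs(nat$p - tail_truth), 3 * nat$se + 1e-9)
})

test_that("predictor series are nonnegative, spiked and extrapolable", {
  cfg <- small_config(seed = 17)
  p <- simulate_predictors(cfg)
  expect_true(all(p$value >= 0))
  expect_setequal(unique(p$variable), c("idp", "density", "hexp"))
  # displacement spike present at the configured year
  idp <- p[p$variable == "idp" & p$governorate == 1, ]
  spike_year <- cfg$predictor_model$idp_spike_year
  expect_gt(idp$value[idp$year == spike_year],
            idp$value[idp$year == spike_year - 1])
  # national series carried once, not per governorate
  expect_true(all(is.na(p$governorate[p$variable == "hexp"])))
})

test_that("three-level binary generator hits its marginal targets", {
  d <- simulate_hierarchical_binary(n = 20000, or = 1, sigma_cluster = 0,
                                    sigma_governorate = 0, p0 = 0.3,
                                    seed = 5)
  expect_equal(mean(d$y), 0.3, tolerance = 0.02)
  # exposure effect visible at or = 3
  d2 <- simulate_hierarchical_binary(n = 20000, or = 3, sigma_cluster = 0,
                                     sigma_governorate = 0, p0 = 0.3,
                                     seed = 5)
  emp_or <- with(d2, (mean(y[x == 1]) / (1 - mean(y[x == 1]))) /
                   (mean(y[x == 0]) / (1 - mean(y[x == 0]))))
  expect_equal(emp_or, 3, tolerance = 0.15)
})
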