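test_that("predictor projection reproduces closed-form lines", {
  # identity-scale series (contains a zero): projection must sit on the
  # least-squares line, here the exact generating line
  ser <- data.frame(variable = "x", governorate = NA_integer_,
                    year = 2000:2018, value = 5 * (0:18))
  pr <- project_predictors(ser, horizon = 2030, seed = 2)
  p30 <- pr$series[pr$series$year == 2030, ]
  expect_equal(p30$value, 5 * 30, tolerance = 1e-8)
  expect_false(p30$observed)
  # constant series: constant projection with no spread
  con <- data.frame(variable = "c", governorate = NA_integer_,
                    year = 2000:2018, value = 7)
  prc <- project_predictors(con, horizon = 2025, seed = 2)
  expect_equal(prc$series$value, rep(7, nrow(prc$series)), tolerance = 1e-10)
  # strictly positive series: log-scale modelling keeps all draws positive
  pos <- data.frame(variable = "p", governorate = NA_integer_,
                    year = 2000:2018, value = exp(rnorm(19, 3, 0.5)))
  prp <- project_predictors(pos, horizon = 2030, seed = 4)
  expect_true(all(unlist(prp$draws) > 0))
})

test_that("short predictor series fall back to carrying the last value forward", {
  ser <- data.frame(variable = "x", governorate = NA_integer_,
                    year = c(2010, 2015), value = c(3, 9))
  expect_warning(pr <- project_predictors(ser, horizon = 2020), "fewer than 3")
  expect_true(all(pr$series$value[!pr$series$observed] == 9))
})

test_that("a single-group trend fit recovers its generating slope", {
  cells <- simulate_coverage_cells(n_groups = 1, n_per_cell = 2000,
                                   mu_alpha = -0.3, sd_alpha = 0,
                                   mu_beta = 0.5, sd_beta = 0, seed = 6)
  fit <- fit_trend(cells, level = "governorate", chains = fast_mcmc$chains,
                   adapt = fast_mcmc$adapt, burnin = fast_mcmc$burnin,
                   iter = fast_mcmc$iter, seed = 8)
  b <- fit$draws[, "beta[1]"]
  expect_lt(abs(mean(b) - 0.5), 3 * sd(b))
  expect_true(fit$converged)
  # logit-link projections live strictly inside the unit interval
  expect_true(all(fit$projection$p > 0 & fit$projection$p < 1))
  expect_true(all(fit$projection$lo > 0 & fit$projection$hi < 1))
})

test_that("a zero-variance predictor is flagged and learns nothing", {
  cells <- simulate_coverage_cells(n_groups = 6, n_per_cell = 400, seed = 4)
  flat <- data.frame(variable = "flat", governorate = NA_integer_,
                     year = 2000:2018, value = 1)
  expect_warning(
    fit <- fit_trend(cells, level = "governorate", predictors = flat,
                     horizon = 2018, chains = 2, adapt = 300, burnin = 500,
                     iter = 1500, seed = 2),
    "zero variance")
  # posterior for the dead coefficient stays close to its vague prior
  expect_gt(sd(fit$draws[, "theta[1]"]), 30)
})

test_that("the hierarchy is exchangeable in the group labels", {
  cells <- simulate_coverage_cells(n_groups = 8, n_per_cell = 500, seed = 9)
  fit1 <- fit_trend(cells, level = "governorate", chains = 2, adapt = 300,
                    burnin = 500, iter = 1500, seed = 3)
  relab <- cells
  perm <- setNames(sample(as.character(1:8)), as.character(1:8))
  relab$stratum <- unname(perm[relab$stratum])
  fit2 <- fit_trend(relab, level = "governorate", chains = 2, adapt = 300,
                    burnin = 500, iter = 1500, seed = 3)
  expect_lt(abs(mean(fit1$draws[, "mu_b"]) - mean(fit2$draws[, "mu_b"])),
            0.05)
  # per-group projections follow their labels
  p1 <- predict(fit1, years = 2030)
  p2 <- predict(fit2, years = 2030)
  for (g in as.character(1:8))
    expect_lt(abs(p1$p[p1$stratum == g] - p2$p[p2$stratum == perm[[g]]]),
              0.05)
})

test_that("DIC is stable across seeds and has nonnegative complexity", {
  cells <- simulate_coverage_cells(n_groups = 6, n_per_cell = 500, seed = 2)
  f1 <- fit_trend(cells, level = "governorate", chains = 2, adapt = 300,
                  burnin = 500, iter = 1500, seed = 1)
  f2 <- fit_trend(cells, level = "governorate", chains = 2, adapt = 300,
                  burnin = 500, iter = 1500, seed = 99)
  d1 <- compute_dic(f1); d2 <- compute_dic(f2)
  expect_gt(d1$pd, 0)
  expect_lt(abs(d1$dic - d2$dic) / abs(d1$dic), 0.05)
  f1$deviance <- NULL
  expect_error(compute_dic(f1), "deviance")
})

test_that("convergence diagnostics catch healthy and stuck chains", {
  # healthy independent draws
  x <- matrix(rnorm(4000), ncol = 4)
  expect_lt(uhcequity:::split_rhat(x), 1.02)
  # two chains stuck at different constants
  bad <- cbind(rep(0, 500), rep(5, 500))
  expect_gt(uhcequity:::split_rhat(bad), 2)
  # on a real fit: report shape and ESS bound
  cells <- simulate_coverage_cells(n_groups = 4, n_per_cell = 300, seed = 5)
  fit <- fit_trend(cells, level = "governorate", chains = 2, adapt = 300,
                   burnin = 400, iter = 800, seed = 4)
  rep <- check_convergence(fit)
  expect_true(all(c("parameter", "rhat", "ess", "pass") %in% names(rep)))
  expect_true(all(rep$ess <= nrow(fit$draws) * 1.05 + 1, na.rm = TRUE))
  expect_type(attr(rep, "overall"), "logical")
})

test_that("attainment report classifies strata against the 80% target", {
  cells <- simulate_coverage_cells(n_groups = 5, n_per_cell = 800,
                                   mu_alpha = 0.3, sd_alpha = 0.6,
                                   mu_beta = 0.5, sd_beta = 0.1,
                                   level = "quintile", seed = 12)
  fit <- fit_trend(cells, level = "quintile", chains = 2, adapt = 500,
                   burnin = 1000, iter = 2000, seed = 6)
  rep <- coverage_gap_report(fit, target = 0.80, year = 2030)
  expect_identical(rep$attains, rep$p >= 0.80)
  expect_equal(nrow(rep), 5)
  # quintile gap is the fitted richest-poorest difference in points
  expect_equal(unique(rep$gap_pp),
               100 * (rep$p[rep$stratum == "5"] - rep$p[rep$stratum == "1"]))
})
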