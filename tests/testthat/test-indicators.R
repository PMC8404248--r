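toy_hh <- function(shares, weights = NULL, size = 1, consumption = 100) {
  n <- length(shares)
  data.frame(record_id = seq_len(n), consumption = consumption,
             food_consumption = consumption * 0.5,
             oop = shares * consumption, hh_size = size,
             weight = weights %||% rep(1, n),
             governorate = 1L, residence = "urban", cluster = seq_len(n),
             year = 2012)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("catastrophic flags follow the strict 10% share rule", {
  shares <- c(0.02, 0.05, 0.08, 0.10, 0.11, 0.15, 0.20, 0.00, 0.09, 0.30)
  hh <- toy_hh(shares)
  fl <- flag_catastrophic(hh)
  # brute-force enumeration: strictly above 10%
  expect_identical(fl, shares > 0.10)
  expect_false(fl[4])  # exactly 10% is not catastrophic
  expect_false(fl[8])  # zero spender
  expect_equal(weighted.mean(fl, hh$weight), 0.4)
  expect_error(flag_catastrophic(toy_hh(0.1, consumption = 0)),
               "consumption")
})

test_that("catastrophic incidence is monotone non-increasing in the threshold", {
  hh <- toy_hh(runif(50, 0, 0.4))
  inc <- sapply(c(0.05, 0.1, 0.15, 0.25, 0.4),
                function(t) mean(flag_catastrophic(hh, t)))
  expect_true(all(diff(inc) <= 0))
})

test_that("alternative catastrophic denominators behave sensibly", {
  hh <- toy_hh(c(0.08, 0.12))
  # non-food denominator halves the base, doubling the effective share
  expect_identical(flag_catastrophic(hh, denominator = "nonfood"),
                   c(TRUE, TRUE))
  expect_error(flag_catastrophic(hh, denominator = "ctp"), "poverty_line")
})

test_that("impoverishment requires crossing the line because of OOP", {
  line <- 100 / 30  # consumption is per 30-day period
  # pre-payment poor: never flagged
  poor <- data.frame(consumption = 80, oop = 50, hh_size = 1)
  expect_false(flag_impoverishment(poor, line))
  # at the line with no OOP: not flagged
  at_line <- data.frame(consumption = 100, oop = 0, hh_size = 1)
  expect_false(flag_impoverishment(at_line, line))
  # 120 down to 90 across a line of 100: flagged
  crosser <- data.frame(consumption = 120, oop = 30, hh_size = 1)
  expect_true(flag_impoverishment(crosser, line))
  expect_error(flag_impoverishment(data.frame(consumption = 1, oop = 0),
                                   line), "size")
  # all-zero OOP implies zero impoverishment incidence
  hh <- toy_hh(rep(0, 30), size = 3)
  expect_false(any(flag_impoverishment(hh, poverty_line = 2)))
})

test_that("weighted quintile assignment matches a brute-force CDF oracle", {
  set.seed(42)
  idx <- rnorm(100)
  w <- runif(100, 0.5, 3)
  q <- assign_wealth_quintiles(idx, w)
  # oracle: invert the weighted CDF at each unit's mass midpoint
  o <- order(idx, seq_along(idx))
  cw <- cumsum(w[o]); W <- sum(w)
  mid <- (cw - w[o] / 2) / W
  oracle <- integer(100)
  oracle[o] <- findInterval(mid, seq(0, 1, 0.2), rightmost.closed = TRUE)
  expect_identical(q, oracle)
  # monotone in the index
  expect_true(all(diff(q[o]) >= 0))
  # scale invariance of weights
  expect_identical(q, assign_wealth_quintiles(idx, 2 * w))
  # five equally weighted distinct units: one per quintile
  expect_identical(assign_wealth_quintiles(c(5, 1, 3, 2, 4)),
                   c(5L, 1L, 3L, 2L, 4L))
  expect_error(assign_wealth_quintiles(rep(1, 10)), "constant")
})

test_that("coverage estimator matches closed forms in simple designs", {
  n <- 200
  set.seed(9)
  rec <- data.frame(year = 2018, governorate = 1L, residence = "urban",
                    cluster = seq_len(n), weight = 1,
                    elig_X = TRUE, y_X = rbinom(n, 1, 0.6))
  est <- estimate_coverage(rec, "X", levels = "national")
  p <- mean(rec$y_X)
  expect_equal(est$p, p)
  # each record its own PSU: SE reduces to sqrt(p(1-p)/(n-1))
  expect_equal(est$se, sqrt(p * (1 - p) / (n - 1)), tolerance = 1e-12)
  # all successes: coverage 1, zero SE, missing off
  rec$y_X <- 1
  est1 <- estimate_coverage(rec, "X", levels = "national")
  expect_equal(est1$p, 1)
  expect_equal(est1$se, 0)
  expect_false(est1$missing)
})

test_that("coverage estimates are invariant to uniform weight rescaling", {
  m <- simulate_mics(small_config(seed = 31))
  a <- estimate_coverage(m, "ANC4", levels = c("national", "quintile"))
  m$weight <- m$weight * 7.3
  b <- estimate_coverage(m, "ANC4", levels = c("national", "quintile"))
  expect_equal(a$p, b$p)
  expect_equal(a$se, b$se)
})

test_that("full immunisation never exceeds any component on its denominator", {
  m <- simulate_mics(small_config(seed = 14))
  on_full_denom <- function(ind) indicator_definition(
    ind, denominator = function(d) d$elig_FULL,
    numerator = function(d) d[[paste0("y_", ind)]] %in% 1)
  defs <- lapply(c("FULL", "BCG", "DTP3", "MSL"), on_full_denom)
  est <- estimate_coverage(m, defs, levels = "national")
  for (yr in unique(est$year)) {
    e <- est[est$year == yr, ]
    expect_lte(e$p[e$indicator == "FULL"],
               min(e$p[e$indicator != "FULL"]) + 1e-12)
  }
})

test_that("empty cells are flagged missing rather than silently zero", {
  m <- simulate_mics(small_config(seed = 3))
  nobody <- indicator_definition("NOBODY",
                                 denominator = function(d) rep(FALSE, nrow(d)),
                                 numerator = function(d) rep(FALSE, nrow(d)))
  est <- estimate_coverage(m, list(nobody), levels = "national")
  expect_true(all(est$missing))
  expect_true(all(is.na(est$p)))
})

test_that("coverage recovers the generating truth within 3 design SEs", {
  cfg <- sim_config(n_governorates = 6, clusters_per_stratum = 8,
                    households_per_cluster = 14, years = 2018,
                    indicator_params = one_indicator(intercept = 0.4,
                                                     residence_gap = -0.6),
                    predictor_effects = no_pred, re_sd = no_noise, seed = 23)
  m <- simulate_mics(cfg)
  est <- estimate_coverage(m, "ANC1", levels = "residence")
  truth <- c(rural = plogis(0.4 - 0.6), urban = plogis(0.4))
  for (s in est$stratum)
    expect_lt(abs(est$p[est$stratum == s] - truth[[s]]),
              3 * est$se[est$stratum == s])
})
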