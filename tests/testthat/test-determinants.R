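test_that("design matrices are dummy-coded against the stated references", {
  rec <- data.frame(mother_age = c("<20", "20-35", ">=36"),
                    mother_edu = c("none", "primary", "higher"),
                    wealth_quintile = c(1, 3, 5),
                    residence = c("urban", "rural", "urban"))
  cov <- list(cov_factor("mother_age", c("<20", "20-35", ">=36")),
              cov_factor("mother_edu",
                         c("none", "primary", "secondary", "higher")),
              cov_factor("wealth_quintile", as.character(1:5)),
              cov_factor("residence", c("urban", "rural")))
  dm <- build_design_matrix(rec, cov)
  # record 1 sits at every reference level: all-zero row
  expect_true(all(dm$X[1, ] == 0))
  # 3-level factor contributes 2 dummies
  expect_equal(sum(dm$map$covariate == "mother_age"), 2)
  expect_equal(ncol(dm$X), 2 + 3 + 4 + 1)
  expect_error(
    build_design_matrix(data.frame(residence = "peri-urban"),
                        list(cov_factor("residence", c("urban", "rural")))),
    "peri-urban")
})

test_that("outcome-specific covariate applicability matches the model plan", {
  # family planning: no antenatal-care or child-sex terms
  fp <- determinant_covariates("FPNS")
  expect_false("anc_visits" %in% sapply(fp, `[[`, "col"))
  # oral rehydration therapy: top antenatal-care category excluded
  ort <- determinant_covariates("ORT")
  anc <- ort[[which(sapply(ort, `[[`, "col") == "anc_visits")]]
  expect_identical(anc$drop, "4")
  # impoverishment: wealth quintile not applicable
  imp <- determinant_covariates("IMPOV")
  expect_false("wealth_quintile" %in% sapply(imp, `[[`, "col"))
  # excluded-level records are dropped with a message
  rec <- data.frame(anc_visits = c("0", "2", "4"))
  expect_message(dm <- build_design_matrix(rec, list(anc)), "dropped")
  expect_equal(sum(dm$keep), 2)
})

test_that("hierarchical logistic fit agrees with a Laplace approximation", {
  skip_if_not_installed("lme4")
  d <- simulate_hierarchical_binary(n = 3000, or = 2, sigma_cluster = 0.4,
                                    sigma_governorate = 0.2, seed = 44)
  fit <- fit_determinants(d, "y",
                          covariates = list(cov_factor("x", c("0", "1"))),
                          chains = 2, adapt = 300, burnin = 500, iter = 1000,
                          seed = 3)
  gl <- lme4::glmer(y ~ x + (1 | cluster) + (1 | governorate), data = d,
                    family = binomial())
  or_mcmc <- fit$or_table$or[fit$or_table$level == "1"]
  or_laplace <- exp(unname(lme4::fixef(gl)["x"]))
  expect_lt(abs(or_mcmc - or_laplace) / or_laplace, 0.05)
  # truth within the credible interval
  row <- fit$or_table[fit$or_table$level == "1", ]
  expect_true(row$lo < 2 && 2 < row$hi)
})

test_that("a generated survey-year effect is recovered for financial outcomes", {
  d <- simulate_hierarchical_binary(n = 4000, or = 1.5, year_or = 2.0,
                                    sigma_cluster = 0.3,
                                    sigma_governorate = 0.15, seed = 21)
  fit <- fit_determinants(d, "y",
                          covariates = list(cov_factor("x", c("0", "1")),
                                            cov_factor("year", c("0", "1"))),
                          chains = 2, adapt = 300, burnin = 500, iter = 1000,
                          seed = 9)
  yr <- fit$or_table[fit$or_table$covariate == "year" &
                       !fit$or_table$reference, ]
  expect_true(yr$lo < 2.0 && 2.0 < yr$hi)
})

test_that("reference swapping inverts odds ratios draw by draw", {
  d <- simulate_hierarchical_binary(n = 1500, or = 2, seed = 10)
  fit <- suppressWarnings(
    fit_determinants(d, "y",
                     covariates = list(cov_factor("x", c("0", "1"))),
                     chains = 2, adapt = 200, burnin = 300, iter = 500,
                     seed = 5))
  k <- match("x:1", fit$map$column)
  before <- exp(fit$draws[, sprintf("b[%d]", k)])
  sw <- swap_reference(fit, "x")
  after <- exp(sw$draws[, sprintf("b[%d]", k)])
  expect_equal(after, 1 / before, tolerance = 1e-12)
  expect_equal(sw$or_table$or[!sw$or_table$reference],
               1 / fit$or_table$or[!fit$or_table$reference],
               tolerance = 1e-10)
  expect_error(swap_reference(fit, "cluster"), "binary")
})

test_that("degenerate and pathological inputs are caught", {
  d <- simulate_hierarchical_binary(n = 40, seed = 2)
  expect_error(fit_determinants(d, "y",
                                covariates = list(cov_factor("x", c("0", "1")))),
               "fewer than 50")
  # separation: outcome constant within a level
  d2 <- simulate_hierarchical_binary(n = 300, seed = 3)
  d2$y[d2$x == 1] <- 1
  w <- capture_warnings(
    fit_determinants(d2, "y",
                     covariates = list(cov_factor("x", c("0", "1"))),
                     chains = 2, adapt = 100, burnin = 100, iter = 200,
                     seed = 1))
  expect_true(any(grepl("separation", w)))
})

test_that("the weighted pseudo-likelihood option recovers the same effect", {
  d <- simulate_hierarchical_binary(n = 800, or = 2, seed = 3)
  d$weight <- runif(800, 0.5, 2)
  f <- suppressWarnings(
    fit_determinants(d, "y", covariates = list(cov_factor("x", c("0", "1"))),
                     weights = "pseudo", chains = 2, adapt = 200,
                     burnin = 200, iter = 400, seed = 2))
  row <- f$or_table[!f$or_table$reference, ]
  expect_true(row$lo < 2 && 2 < row$hi)
})

test_that("near-zero generating variance yields near-zero variance components", {
  d <- simulate_hierarchical_binary(n = 4000, or = 1.5, sigma_cluster = 0,
                                    sigma_governorate = 0, seed = 31)
  fit <- fit_determinants(d, "y",
                          covariates = list(cov_factor("x", c("0", "1"))),
                          chains = 2, adapt = 300, burnin = 500, iter = 1000,
                          seed = 7)
  expect_lt(fit$varcomp$variance[fit$varcomp$component == "cluster"], 0.05)
  expect_lt(fit$varcomp$variance[fit$varcomp$component == "governorate"],
            0.05)
})
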