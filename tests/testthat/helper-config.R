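# small, fast configurations used across tests

small_config <- function(seed = 1L, ...) {
  sim_config(n_governorates = 4, clusters_per_stratum = 3,
             households_per_cluster = 8, seed = seed, ...)
}

# single-indicator parameter table with chosen effects and no derived slot
one_indicator <- function(name = "ANC1", intercept = 0, slope = 0,
                          wealth_gradient = 0, residence_gap = 0) {
  data.frame(indicator = name, intercept = intercept, slope = slope,
             wealth_gradient = wealth_gradient, residence_gap = residence_gap,
             derived = FALSE)
}

no_noise <- c(cluster = 0, governorate = 0)
no_pred <- c(idp = 0, density = 0, hexp = 0)

# quick MCMC settings for model-fitting tests
fast_mcmc <- list(chains = 2, adapt = 300, burnin = 500, iter = 1000)
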