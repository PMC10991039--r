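# Shared fixtures: small, fast simulation settings for the comparison-data
# pipelines, and a one-call data generator for a study condition.

quick <- list(n_rep = 60L, n_population = 2000L)

make_condition_data <- function(k, n, vpf, rho = 0, primary = "medium",
                                cross = "zero", seed = 1L) {
  spec <- condition_spec(k, n, vpf, rho, primary, cross)
  model <- build_population(spec, seed = seed)
  simulate_factor_data(model, n, seed = seed + 1000L)
}

# exact equicorrelation matrix, used for closed-form eigen checks
equicorr <- function(p, r) {
  m <- matrix(r, p, p)
  diag(m) <- 1
  m
}
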