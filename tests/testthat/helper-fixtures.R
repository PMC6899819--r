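# Shared fixtures: small networks, short chain regimes, and a fake-fit
# constructor for estimand tests that do not need real MCMC.

two_arm_net <- function(events = c(5, 9, 2, 7), size = c(50, 50, 40, 40)) {
  nma_network(data.frame(
    study = c(1, 1, 2, 2), treatment = c(1, 2, 1, 3),
    events = events, size = size))
}

# three treatments, four two-arm studies, all containing the reference
star_net <- function() {
  nma_network(data.frame(
    study = rep(1:4, each = 2),
    treatment = c(1, 2, 1, 3, 1, 2, 1, 3),
    events = c(10, 14, 8, 16, 12, 18, 9, 13),
    size = rep(60, 8)))
}

# quick chain regime for tests that only need a roughly-right posterior
cfg_quick <- function(seed = 42) {
  chain_config(burn_in = 1500, post_burn = 6000, thin = 3, seed = seed,
               n_adapt = 500)
}

# moderate regime for tests that compare posteriors between models
cfg_medium <- function(seed = 42) {
  chain_config(burn_in = 4000, post_burn = 20000, thin = 5, seed = seed,
               n_adapt = 1000)
}

# Build an object with the nma_fit interface from a given draws matrix, so
# estimand and diagnostic code can be exercised against known inputs.
fake_fit <- function(draws, spec = model_spec(3), n_chains = 1) {
  structure(list(draws = draws, params = colnames(draws),
                 chain = rep(seq_len(n_chains),
                             each = nrow(draws) / n_chains),
                 spec = spec, config = chain_config(seed = 1),
                 network = NULL, data_hash = "fake"),
            class = "nma_fit")
}

# random valid parameter state for property tests
random_state <- function(spec, net, rng = 1) {
  set.seed(rng)
  K <- net$n_treatments
  n <- net$n_studies
  parameter_state(
    alpha = rnorm(n, -1, 0.5),
    delta = cbind(0, matrix(rnorm(n * (K - 1), 0, 0.4), n)),
    eta = matrix(rnorm(n * K, 0, 0.3), n),
    theta = matrix(rnorm(n * K, -1, 0.5), n),
    mu_c = c(0, rnorm(K - 1, 0, 0.5)),
    mu_a = rnorm(K, -1, 0.3),
    sigma_c2 = runif(1, 0.05, 0.5),
    sigma_a2 = runif(1, 0.1, 1),
    rho_a = runif(1, 0, 0.8))
}
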