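# Shared fixtures: small deterministic systems used across test files.

make_ci_series <- function(n = 200, b1 = 1, b2 = 1, seed = 42) {
  simulate_system(dgp_spec("CI1", n_obs = n, b1 = b1, b2 = b2, seed = seed))
}

make_walks <- function(n = 200, seed = 42) {
  simulate_system(dgp_spec("I1", n_obs = n, seed = seed))
}

# rejection rate of a predicate over seeded replications
rejection_rate <- function(n_reps, master_seed, fun) {
  seeds <- cointsim:::spawn_seeds(master_seed, n_reps)
  mean(vapply(seeds, fun, logical(1)))
}
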