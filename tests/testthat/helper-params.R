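# Base parameter set used across tests: the model's reference conditions
# (lambda = 0.6, eta = 0.4, d = 2, c = 0.1) on a small lattice.
base_params <- function(r = 3, L = 20, steps = 200, burn_in = min(100, steps - 1),
                        nu = 1e-4, q = 1, topology = "mixed", seed = 1L,
                        lambda = 0.6, eta = 0.4, ...) {
  sim_params(lambda = lambda, eta = eta, d = 2, r = r, cost = 0.1, nu = nu,
             q = q, L = L, topology = topology, steps = steps,
             burn_in = burn_in, seed = seed, ...)
}

# Independent brute-force payoff average over an explicit group: score every
# member with the pot-sharing rule spelled out longhand.
brute_group_payoffs <- function(is_c, r, cost) {
  k <- length(is_c)
  pot <- r * cost * sum(is_c)
  pot / k - cost * is_c
}
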