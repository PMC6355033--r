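# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Default three-level toy chromosome and its annealed model + kinetics.
toy_default <- function() cached("toy_default", {
  profile <- toy_profile()
  model <- toy_msm(profile, beta = 10)
  kin <- kinetics(model)
  list(profile = profile, model = model, kinetics = kin)
})

# Small two-level toy (branching 2 x 3) for cheaper end-to-end checks.
toy_small <- function() cached("toy_small", {
  spec <- toy_spec(n_loci = 120, branching = c(2, 3),
                   barrier_heights = c(2, 1))
  profile <- toy_profile(spec)
  model <- toy_msm(profile, beta = 10)
  kin <- kinetics(model)
  list(profile = profile, model = model, kinetics = kin)
})

# Reversible chain from symmetric positive weights.
chain_from_weights <- function(W) {
  diag(W) <- 0
  build_msm(energy_landscape(-log(W)), beta = 1)
}

# Random reversible chain on n states (dense, irreducible).
random_chain <- function(n, seed) {
  set.seed(seed)
  W <- matrix(runif(n * n, 0.05, 1), n, n)
  chain_from_weights((W + t(W)) / 2)
}

# Uniform chain: all off-diagonal weights equal.
uniform_chain <- function(n) chain_from_weights(matrix(1, n, n))

# Two weakly coupled cliques of size `m` with cross-link weight `eps`
# relative to intra-clique weight 1.
two_clique_chain <- function(m = 3, eps = 1e-3) {
  n <- 2 * m
  W <- matrix(eps, n, n)
  W[1:m, 1:m] <- 1
  W[(m + 1):n, (m + 1):n] <- 1
  chain_from_weights(W)
}
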