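# Independent oracles used to cross-check the package's linear-algebra
# paths. These deliberately avoid the implementation under test: hitting
# times come from direct stochastic simulation, optima from exhaustive
# enumeration, kernels from direct tabulation, p-values from permutation.

# Monte-Carlo mean first-passage time: simulate `nwalks` random walks from
# `from` until they hit `to`, stepping all walkers in parallel.
oracle_mfpt_sim <- function(P, from, to, nwalks = 1e5, seed = 42,
                            max_steps = 1e6) {
  set.seed(seed)
  cum <- t(apply(P, 1, cumsum))
  state <- rep(as.integer(from), nwalks)
  steps <- integer(nwalks)
  alive <- rep(TRUE, nwalks)
  t <- 0L
  while (any(alive) && t < max_steps) {
    t <- t + 1L
    idx <- which(alive)
    u <- runif(length(idx))
    nxt <- vapply(seq_along(idx), function(w)
      findInterval(u[w], cum[state[idx[w]], ]) + 1L, integer(1))
    state[idx] <- nxt
    hit <- nxt == to
    steps[idx[hit]] <- t
    alive[idx[hit]] <- FALSE
  }
  list(mean = mean(steps), se = sd(steps) / sqrt(nwalks))
}

# Exhaustive global minimum of the metastability index over all hub sets
# of size n (for small chains).
oracle_exhaustive_rho <- function(gamma, n) {
  sets <- utils::combn(nrow(gamma), n)
  rhos <- apply(sets, 2, function(M) metastability_index(gamma, M))
  list(rho = min(rhos), members = sort(sets[, which.min(rhos)]))
}

# Direct tabulation of the truncated, normalized 2D Gaussian kernel.
oracle_gauss_kernel2d <- function(sigma, r) {
  k1 <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k1 <- k1 / sum(k1)
  outer(k1, k1)
}

# Permutation p-value for Pearson correlation.
oracle_perm_p <- function(x, y, nperm = 1e4, seed = 7) {
  set.seed(seed)
  obs <- abs(cor(x, y))
  hits <- sum(replicate(nperm, abs(cor(x, sample(y))) >= obs))
  (hits + 1) / (nperm + 1)
}
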