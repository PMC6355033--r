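test_that("metastability index reproduces hand-computed and designed cases", {
  g3 <- kinetics(uniform_chain(3))$gamma
  # uniform 3-chain, M = {1,2}: numerator 3/4, denominator max(3/4, 3/4)
  expect_equal(metastability_index(g3, c(1, 2)), 1)
  # two weakly coupled cliques, one hub per clique: strongly metastable
  mc <- two_clique_chain(m = 3, eps = 1e-3)
  gc <- kinetics(mc)$gamma
  expect_lt(metastability_index(gc, c(1, 4)), 0.1)
  expect_error(metastability_index(g3, 1:3), "non-hub")
  expect_error(metastability_index(g3, 1), "at least 2")
  expect_error(metastability_index(g3, c(1, 1)), "duplicated")
})

test_that("seed pair starts from the stationary maximum and minimizes rho", {
  m <- two_clique_chain(m = 3, eps = 1e-3)
  kin <- kinetics(m)
  sp <- seed_pair(m, kin$gamma)
  expect_equal(sp$members[1] <= 3, sp$members[2] > 3)  # one hub per clique
  # unique stationary maximum is chosen as a
  mr <- random_chain(6, seed = 21)
  kr <- kinetics(mr)
  spr <- seed_pair(mr, kr$gamma)
  a <- which.max(mr$stationary)
  expect_true(a %in% spr$members)
  # exhaustive check: b attains the minimum over all candidates
  rhos <- vapply(setdiff(1:6, a), function(b)
    metastability_index(kr$gamma, c(a, b)), numeric(1))
  expect_equal(spr$rho, min(rhos))
})

test_that("MC optimization is deterministic under a fixed seed and never worsens", {
  m <- random_chain(8, seed = 2)
  g <- kinetics(m)$gamma
  set.seed(5); o1 <- mc_optimize_hubs(g, c(1, 2), iters = 200)
  set.seed(5); o2 <- mc_optimize_hubs(g, c(1, 2), iters = 200)
  expect_identical(o1$members, o2$members)
  expect_identical(o1$rho, o2$rho)
  init_rho <- metastability_index(g, c(1, 2))
  expect_lte(o1$rho, init_rho)
})

test_that("MC search attains the exhaustive optimum on small chains", {
  m <- random_chain(8, seed = 4)
  g <- kinetics(m)$gamma
  exact <- oracle_exhaustive_rho(g, 2)
  set.seed(1)
  o <- mc_optimize_hubs(g, c(1, 2), iters = 500)
  expect_equal(o$rho, exact$rho)
  expect_identical(o$members, exact$members)
})

test_that("two-well toy: optimal pair straddles the wells and beats any triple", {
  spec <- toy_spec(n_loci = 60, branching = 2, barrier_heights = 2)
  prof <- toy_profile(spec)
  model <- toy_msm(prof, beta = 10)
  kin <- kinetics(model)
  rp <- rho_profile(model, gamma = kin$gamma, n_max = 3, iters = 300, seed = 2)
  top <- prof$basin_labels[, 1]
  h2 <- rp$hubs[[1]]
  expect_lt(rp$rho[1], 1)
  expect_equal(length(unique(top[h2])), 2)   # hubs in distinct wells
  expect_lt(rp$rho[1], rp$rho[2])            # rho(2) < rho(3)
})

test_that("profile covers contiguous sizes and hierarchy selection applies its rules", {
  m <- random_chain(12, seed = 8)
  kin <- kinetics(m)
  rp <- rho_profile(m, gamma = kin$gamma, n_max = 5, iters = 50, seed = 1)
  expect_equal(rp$sizes, 2:5)
  expect_equal(length(rp$hubs), 4)
  expect_true(all(vapply(seq_along(rp$hubs),
                         function(k) length(rp$hubs[[k]]) == rp$sizes[k],
                         logical(1))))
  # synthetic profile with minima at {2,5,8,12,27}, all deep: the doubling
  # rule keeps [5, 12, 27] after dropping the trivial size 2
  sizes <- 2:30
  rho <- rep(1, length(sizes))
  rho[match(c(2, 5, 8, 12, 27), sizes)] <- c(0.1, 0.3, 0.35, 0.3, 0.5)
  fake <- structure(list(sizes = sizes, rho = rho,
                         hubs = lapply(sizes, seq_len), beta = 8),
                    class = "rho_profile")
  lev <- select_hierarchy(fake)
  expect_equal(lev$sizes, c(5, 12, 27))
  # all minima above threshold: empty result, not an error
  flat <- structure(list(sizes = sizes, rho = rep(1, length(sizes)) -
                           0.01 * (sizes %in% c(5, 12)),
                         hubs = lapply(sizes, seq_len), beta = 8),
                    class = "rho_profile")
  expect_length(select_hierarchy(flat)$sizes, 0)
  # keep-trivial retains size 2
  expect_equal(select_hierarchy(fake, keep_trivial = TRUE)$sizes,
               c(2, 5, 12, 27))
  # skip-first override (largest-chromosome rule): the second-smallest
  # minimum becomes the first level, and the doubling rule runs from it
  expect_equal(select_hierarchy(fake, skip_first = TRUE)$sizes, c(8, 27))
  # shallow non-separated dip (0.5 flanked by 0.55) is not a level
  rho2 <- rep(1, length(sizes))
  rho2[match(c(2, 3, 4, 5, 6), sizes)] <- c(0.001, 0.55, 0.5, 0.55, 0.002)
  dip <- structure(list(sizes = sizes, rho = rho2,
                        hubs = lapply(sizes, seq_len), beta = 10),
                   class = "rho_profile")
  expect_equal(select_hierarchy(dip, keep_trivial = TRUE)$sizes, c(2, 6))
})

test_that("MC equals exhaustive enumeration across chains and seeds", {
  # criterion-scale check lives in test-acceptance; here a quick sweep over
  # chain families at n = 2 and 3
  for (cfg in list(list(n = 6, seed = 31), list(n = 10, seed = 32))) {
    m <- random_chain(cfg$n, cfg$seed)
    g <- kinetics(m)$gamma
    for (nh in 2:3) {
      exact <- oracle_exhaustive_rho(g, nh)
      hits <- 0L
      for (s in 1:20) {
        set.seed(s)
        o <- mc_optimize_hubs(g, seq_len(nh), iters = 500)
        hits <- hits + (abs(o$rho - exact$rho) < 1e-12)
      }
      expect_gte(hits, 19L)
    }
  }
})
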