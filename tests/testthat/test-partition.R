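test_that("committors solve the gambler's-ruin midpoint and boundary conditions", {
  # path 1-2-3, hubs {1,3}: interior point splits 50/50
  W <- matrix(c(0, 1, 1e-12, 1, 0, 1, 1e-12, 1, 0), 3, 3)
  m <- chain_from_weights(W)
  soft <- committor_probabilities(m, c(1, 3))
  expect_equal(unname(soft$q[2, 1]), 0.5, tolerance = 1e-9)
  expect_equal(soft$q[1, ], c(1, 0), ignore_attr = TRUE)
  expect_equal(soft$q[3, ], c(0, 1), ignore_attr = TRUE)
  # partition of unity on a 20-state chain with 3 hubs
  m20 <- random_chain(20, seed = 13)
  s20 <- committor_probabilities(m20, c(2, 9, 17))
  expect_equal(rowSums(s20$q), rep(1, 20), tolerance = 1e-10)
  expect_true(all(s20$q >= -1e-12 & s20$q <= 1 + 1e-12))
})

test_that("hard assignment takes the argmax with genomic tie-breaking", {
  soft <- structure(list(q = rbind(c(0.7, 0.2, 0.1),
                                   c(0.5, 0.5, 0),
                                   c(0.1, 0.2, 0.7)),
                         hubs = c(4L, 9L, 15L)),
                    class = "soft_partition")
  hp <- hard_assign(soft)
  expect_equal(hp$assignment, c(1L, 1L, 3L))
  # partition sizes sum to number of loci
  m <- toy_small()$model
  soft2 <- committor_probabilities(m, c(10, 50, 100))
  hp2 <- hard_assign(soft2)
  expect_equal(length(hp2$assignment), m$n_states)
  expect_equal(sum(table(hp2$assignment)), m$n_states)
})

test_that("hard partitions recover toy ground truth at every level", {
  td <- toy_default()
  rp <- rho_profile(td$model, gamma = td$kinetics$gamma, n_max = 20,
                    iters = 500, seed = 3)
  lev <- select_hierarchy(rp, keep_trivial = TRUE)
  expect_true(all(c(2, 6, 18) %in% lev$sizes))
  for (k in seq_along(lev$sizes)) {
    truth <- td$profile$basin_labels[, k]
    hp <- hard_assign(committor_probabilities(td$model, lev$hubs[[k]]))
    tab <- table(hp$assignment, truth)
    agreement <- sum(apply(tab, 2, max)) / length(truth)
    expect_gte(agreement, 0.95)
  }
})

test_that("toy hard boundaries are stable across annealing levels", {
  prof <- toy_small()$profile
  bounds <- lapply(c(6, 8, 10), function(beta) {
    m <- toy_msm(prof, beta = beta)
    hubs <- vapply(split(seq_len(120), prof$basin_labels[, 2]),
                   function(ix) ix[which.min(prof$energy[ix])], integer(1))
    hp <- hard_assign(committor_probabilities(m, sort(unname(hubs))))
    partition_intervals(hp)$end
  })
  # boundaries agree to within one bin: the locus exactly on a barrier
  # top is a 50/50 committor case whose side can flip with beta
  expect_equal(length(bounds[[1]]), length(bounds[[2]]))
  expect_equal(length(bounds[[2]]), length(bounds[[3]]))
  expect_lte(max(abs(bounds[[1]] - bounds[[2]])), 1)
  expect_lte(max(abs(bounds[[2]] - bounds[[3]])), 1)
})

test_that("NMI matches closed forms, is symmetric and relabel-invariant", {
  a <- rep(1:3, each = 10)
  expect_equal(normalized_mutual_information(a, a, "sym"), 1)
  expect_equal(normalized_mutual_information(a, a, "paper"), 0.5)
  # independent 2x2 uniform contingency: zero mutual information
  p1 <- c(1, 1, 2, 2); p2 <- c(1, 2, 1, 2)
  expect_equal(normalized_mutual_information(p1, p2), 0)
  set.seed(4)
  b <- sample(rep(1:4, times = c(5, 10, 7, 8)))
  expect_equal(normalized_mutual_information(a, b),
               normalized_mutual_information(b, a))
  relab <- c(3L, 1L, 2L)[a]
  expect_equal(normalized_mutual_information(a, b),
               normalized_mutual_information(relab, b))
  expect_error(normalized_mutual_information(rep(1, 30), a), "entropy")
})

test_that("RMI calibration is exact", {
  expect_identical(rescaled_mi(0.77), 0)
  expect_identical(rescaled_mi(1.0), 1)
  expect_equal(rescaled_mi(0.885), 0.5)
})

test_that("random-boundary baseline is reproducible and exact for singletons", {
  v1 <- random_boundary_baseline(data.frame(n_loci = 100, k = 5),
                                 samples = 20, seed = 9)
  v2 <- random_boundary_baseline(data.frame(n_loci = 100, k = 5),
                                 samples = 20, seed = 9)
  expect_identical(as.numeric(v1), as.numeric(v2))
  # k = n_loci: only one scheme exists, NMI 1 for every sample
  v3 <- random_boundary_baseline(data.frame(n_loci = 12, k = 12),
                                 samples = 5, seed = 1)
  expect_equal(as.numeric(v3), 1)
  expect_error(random_boundary_baseline(data.frame(n_loci = 10, k = 1),
                                        samples = 2, seed = 1), "entropy")
})

test_that("synthetic genome scheme has the published granularity", {
  sch <- synthetic_genome_scheme()
  expect_equal(nrow(sch), 23)
  expect_equal(sum(sch$k), 539)
  expect_true(all(sch$k >= 1 & sch$k <= sch$n_loci))
  mean_size_mbp <- sum(sch$n_loci) * 50000 / 539 / 1e6
  expect_gt(mean_size_mbp, 5); expect_lt(mean_size_mbp, 6.5)
})

test_that("hierarchical labels nest child partitions under their majority parent", {
  parent <- hard_partition(rep(c(1, 2), each = 20))
  child <- hard_partition(rep(c(1, 2, 3, 4), each = 10))
  lab <- hierarchy_labels(list(parent, child))
  expect_equal(lab[[1]], c("1", "2"))
  expect_equal(lab[[2]], c("1.1", "1.2", "2.1", "2.2"))
})
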