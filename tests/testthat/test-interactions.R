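test_that("soft effective flux conserves column sums and respects blocks", {
  m <- random_chain(12, seed = 17)
  soft <- committor_probabilities(m, c(3, 7, 11))
  eff <- effective_flux_soft(soft, m)
  # column sums of the raw matrix equal the hub stationary weights
  expect_equal(colSums(eff$F_raw), m$stationary[c(3, 7, 11)],
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(eff$F, t(eff$F))
  # two disconnected cliques (tiny bridge), one hub each: no cross flux
  mc <- two_clique_chain(m = 4, eps = 1e-14)
  sc <- committor_probabilities(mc, c(1, 5))
  ec <- effective_flux_soft(sc, mc)
  expect_lt(ec$F[1, 2] / ec$F[1, 1], 1e-10)
})

test_that("toy effective interactions are strongest within parent basins", {
  td <- toy_default()
  prof <- td$profile
  # hubs at the 6 mid-level well bottoms
  hubs <- sort(vapply(split(seq_len(500), prof$basin_labels[, 2]),
                      function(ix) ix[which.min(prof$energy[ix])], integer(1)))
  soft <- committor_probabilities(td$model, unname(hubs))
  eff <- effective_flux_soft(soft, td$model)
  Fm <- eff$F; diag(Fm) <- NA
  parent <- rep(1:2, each = 3)
  idx <- which(upper.tri(Fm), arr.ind = TRUE)
  ord <- idx[order(-Fm[idx]), , drop = FALSE]
  # the strongest off-diagonal interactions are the adjacent same-parent
  # pairs; every cross-parent pair ranks below every adjacent same-parent
  # pair (distant same-parent pairs decay to the cross-parent scale)
  adjacent_same <- abs(ord[, 1] - ord[, 2]) == 1 &
    parent[ord[, 1]] == parent[ord[, 2]]
  expect_true(all(adjacent_same[1:4]))
  cross <- parent[ord[, 1]] != parent[ord[, 2]]
  expect_gt(min(Fm[ord[adjacent_same, , drop = FALSE]]),
            max(Fm[ord[cross, , drop = FALSE]]))
})

test_that("hard effective flux is an exact block sum of the flux", {
  # 4 loci, uniform flux over the 12 ordered off-diagonal pairs
  flux <- matrix(1 / 12, 4, 4); diag(flux) <- 0
  parts <- hard_partition(c(1, 1, 2, 2))
  eff <- effective_flux_hard(parts, flux)
  expect_equal(eff$F[1, 2], 4 / 12)      # 4 ordered cross pairs per block
  expect_equal(eff$F[1, 1], 2 / 12)
  expect_equal(sum(eff$F), 1, tolerance = 1e-12)
  expect_equal(eff$F, t(eff$F))
  m <- random_chain(9, seed = 23)
  p9 <- hard_partition(rep(1:3, each = 3))
  e9 <- effective_flux_hard(p9, m$flux)
  expect_equal(sum(e9$F), sum(m$flux), tolerance = 1e-12)
  expect_error(effective_flux_hard(hard_partition(c(1, 2)), flux),
               "unassigned")
})

test_that("soft and hard coarse-graining rank the same top pairs on a metastable toy", {
  td <- toy_small()
  prof <- td$profile
  hubs <- sort(vapply(split(seq_len(120), prof$basin_labels[, 2]),
                      function(ix) ix[which.min(prof$energy[ix])], integer(1)))
  soft <- committor_probabilities(td$model, unname(hubs))
  effs <- effective_flux_soft(soft, td$model)
  effh <- effective_flux_hard(hard_assign(soft), td$model$flux)
  top_pairs <- function(Fm, k) {
    idx <- which(upper.tri(Fm), arr.ind = TRUE)
    idx <- idx[order(-Fm[idx]), , drop = FALSE]
    paste(idx[seq_len(k), 1], idx[seq_len(k), 2])
  }
  # the clearly separated strong pairs (adjacent same-parent) agree as a
  # set; the weak tail is numerically degenerate under symmetry, so its
  # internal order is not compared
  expect_setequal(top_pairs(effs$F, 4), top_pairs(effh$F, 4))
  expect_gt(cor(effs$F[upper.tri(effs$F)], effh$F[upper.tri(effh$F)],
                method = "spearman"), 0.9)
})

test_that("layer classification ranks, caps and partitions pairs", {
  set.seed(6)
  Fm <- matrix(0, 5, 5)
  Fm[upper.tri(Fm)] <- sample(10)
  Fm <- Fm + t(Fm)
  lay <- classify_layers(Fm, n_scaffold = 2,
                         layer_percentiles = c(20, 50, 70, 100))
  expect_equal(sum(lay$layer == "scaffold"), 2)
  top2 <- lay$F[lay$layer == "scaffold"]
  expect_setequal(top2, sort(Fm[upper.tri(Fm)], decreasing = TRUE)[1:2])
  # bands partition the remaining pairs with no overlap or gap
  expect_equal(sum(table(lay$layer)), 10)
  expect_equal(as.integer(table(lay$layer)[c("1", "2", "3")]), c(3L, 2L, 3L))
  expect_error(classify_layers(Fm, n_scaffold = 11), "exceeds")
  # deterministic tie handling: ties broken by pair index
  Ft <- matrix(0, 4, 4); Ft[upper.tri(Ft)] <- c(5, 5, 3, 2, 1, 1)
  Ft <- Ft + t(Ft)
  lt <- classify_layers(Ft, n_scaffold = 2, layer_percentiles = c(30, 100))
  expect_equal(lt$F[lt$layer == "scaffold"], c(5, 5))
})

test_that("affinity reproduces closed forms and scale invariance", {
  # two partitions: C = 2 exactly
  f <- matrix(0, 4, 4)
  f[1:2, 3:4] <- 3; f[3:4, 1:2] <- 3; f[1, 2] <- f[2, 1] <- 7
  cm <- contact_matrix(f, resolution = 50000)
  aff <- affinity_matrix(cm, hard_partition(c(1, 1, 2, 2)))
  expect_equal(aff$C[1, 2], 2)
  expect_equal(sum(aff$P_marginal), 1, tolerance = 1e-12)
  # product-structured counts across many partitions: independence gives
  # C near 1 (exactly 1 up to the self-pair exclusion in the marginals,
  # an O(w_A/S) correction)
  set.seed(8)
  w <- runif(30, 0.5, 2)
  fb <- outer(w, w); diag(fb) <- 0
  cmb <- contact_matrix(fb, resolution = 50000)
  affb <- affinity_matrix(cmb, hard_partition(1:30))
  expect_equal(affb$C[upper.tri(affb$C)], rep(1, choose(30, 2)),
               tolerance = 0.06)
  aff2 <- affinity_matrix(contact_matrix(fb * 17, resolution = 50000),
                          hard_partition(1:30))
  expect_equal(aff2$C, affb$C, tolerance = 1e-12)
  # threshold report
  pairs <- high_affinity_pairs(aff, threshold = 1.5)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$C, 2)
})

test_that("component extraction finds planted clusters", {
  pairs <- data.frame(a = c(1, 2, 4), b = c(2, 3, 5),
                      F = c(3, 2, 1),
                      layer = factor(c("scaffold", "1", "below"),
                                     levels = c("scaffold", "1", "2", "below")))
  comp <- interaction_components(pairs, n_nodes = 6)
  expect_equal(comp[1], comp[2])
  expect_equal(comp[2], comp[3])
  expect_false(comp[4] == comp[5])   # below-layer edge ignored
  expect_equal(comp[1], 1)           # largest component labelled 1
})
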