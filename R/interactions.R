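#' Effective interactions between soft partitions (single chromosome)
#'
#' `F_ab = sum_i q_a(i) pi_ib`: the flux of probes into hub `b` weighted
#' by the committor membership of the source locus in partition `a` — the
#' exact, committor-resolved coarse-grained flux on one chromosome. The
#' raw matrix is not exactly symmetric; the reported matrix is the
#' symmetrization `(F + t(F)) / 2` with the raw values retained.
#'
#' @param soft a [committor_probabilities()] result.
#' @param model the matching [chrom_msm()].
#' @return object of class `effective_interactions`: list with `F`
#'   (symmetrized), `F_raw`, `mode = "soft_intra"`, `hubs`.
#' @export
effective_flux_soft <- function(soft, model) {
  if (nrow(soft$q) != model$n_states)
    stop("soft partition and model dimensions differ")
  Fr <- t(soft$q) %*% model$flux[, soft$hubs, drop = FALSE]
  dimnames(Fr) <- list(colnames(soft$q), colnames(soft$q))
  structure(list(F = (Fr + t(Fr)) / 2, F_raw = Fr, mode = "soft_intra",
                 hubs = soft$hubs),
            class = "effective_interactions")
}

#' Effective interactions between hard partitions (mean-field, genome)
#'
#' `F_AB = sum_i theta_A(i) sum_j pi_ij theta_B(j)`: block sums of the
#' flux matrix by partition pair. With the flux normalized over all
#' ordered off-diagonal pairs, the total over partition pairs (diagonal
#' included) equals the total flux exactly. This is the mean-field
#' coarse-graining used genome-wide, where committors are impractical.
#'
#' @param parts a [hard_partition()] over all loci of the flux matrix.
#' @param flux symmetric flux matrix (e.g. `model$flux`, or a genome-wide
#'   flux built from concatenated contact maps).
#' @return object of class `effective_interactions` with exact symmetric `F`.
#' @export
effective_flux_hard <- function(parts, flux) {
  a <- parts$assignment
  if (length(a) != nrow(flux)) stop("unassigned loci present")
  k <- parts$k
  Theta <- matrix(0, length(a), k)
  Theta[cbind(seq_along(a), a)] <- 1
  Fm <- t(Theta) %*% flux %*% Theta
  Fm <- (Fm + t(Fm)) / 2
  structure(list(F = Fm, F_raw = Fm, mode = "hard_genome", hubs = parts$hubs),
            class = "effective_interactions")
}

#' @export
print.effective_interactions <- function(x, ...) {
  cat(sprintf("<effective_interactions> %d partitions (%s), total F = %.6g\n",
              nrow(x$F), x$mode, sum(x$F)))
  invisible(x)
}

#' Classify interaction strengths into layers
#'
#' Ranks unordered partition pairs by effective interaction (descending;
#' ties by value then pair index) and labels the strongest `n_scaffold`
#' pairs as the scaffold layer; subsequent percentile bands become layers
#' 1, 2, ...; everything weaker is `"below"`. The significance set used
#' for major-cluster extraction is scaffold plus layer 1.
#'
#' @param eff an `effective_interactions` object (or plain symmetric
#'   matrix).
#' @param n_scaffold number of scaffold pairs (default 2000).
#' @param layer_percentiles upper percentile bound of each successive
#'   layer, in percent (default `c(1.35, 1.5, 1.7, 2.0)`; the scaffold cap
#'   at 1.35% applies only when it is reached before `n_scaffold` pairs —
#'   the count rule takes precedence, as in the published thresholds).
#' @param include_diagonal rank intra-partition (diagonal) pairs too
#'   (default FALSE).
#' @return data frame of pairs: `a`, `b`, `F`, `layer` (factor with
#'   levels scaffold, 1, 2, ..., below).
#' @export
classify_layers <- function(eff, n_scaffold = 2000,
                            layer_percentiles = c(1.35, 1.5, 1.7, 2.0),
                            include_diagonal = FALSE) {
  Fm <- if (inherits(eff, "effective_interactions")) eff$F else eff
  idx <- which(upper.tri(Fm, diag = include_diagonal), arr.ind = TRUE)
  npair <- nrow(idx)
  if (n_scaffold > npair) stop("n_scaffold exceeds the number of pairs")
  v <- Fm[idx]
  ord <- order(-v, idx[, 1], idx[, 2])
  ranks <- integer(npair); ranks[ord] <- seq_len(npair)
  bounds <- c(n_scaffold, pmax(n_scaffold, round(layer_percentiles[-1] / 100 * npair)))
  labels <- c("scaffold", as.character(seq_along(layer_percentiles[-1])))
  layer <- rep("below", npair)
  lo <- 0
  for (b in seq_along(bounds)) {
    layer[ranks > lo & ranks <= bounds[b]] <- labels[b]
    lo <- bounds[b]
  }
  data.frame(a = idx[, 1], b = idx[, 2], F = v,
             layer = factor(layer, levels = c(labels, "below")))[order(ranks), ]
}

#' Affinity (observed over expected) between partitions
#'
#' From raw (unsmoothed) genome counts: the observed joint probability
#' `P(A&B)` is the fraction of inter-partition counts falling on the
#' ordered pair (A, B); the marginal `P(A) = sum_{Y != A} P(A&Y)` sums to
#' 1 over partitions; the affinity `C_AB = P(A&B) / (P(A) P(B))` is the
#' observed-to-expected ratio. `C > 1` marks associated partitions.
#'
#' @param counts genome [contact_matrix()] (raw counts).
#' @param parts a [hard_partition()] over its loci.
#' @return object of class `affinity`: list with `C` (NA diagonal),
#'   `P_joint`, `P_marginal`.
#' @export
affinity_matrix <- function(counts, parts) {
  f <- if (inherits(counts, "contact_matrix")) counts$counts else counts
  a <- parts$assignment
  if (length(a) != nrow(f)) stop("partition does not cover the count matrix")
  k <- parts$k
  Theta <- matrix(0, length(a), k)
  Theta[cbind(seq_along(a), a)] <- 1
  block <- t(Theta) %*% f %*% Theta       # ordered-pair block sums
  diag(block) <- 0                        # distinct partitions only
  tot <- sum(block)
  if (tot <= 0) stop("no inter-partition counts")
  P_joint <- block / tot
  P_marg <- rowSums(P_joint)
  if (any(P_marg == 0))
    warning("partition(s) with zero inter-partition counts: affinity undefined there")
  C <- P_joint / outer(P_marg, P_marg)
  diag(C) <- NA_real_
  structure(list(C = C, P_joint = P_joint, P_marginal = P_marg),
            class = "affinity")
}

#' @export
print.affinity <- function(x, ...) {
  cat(sprintf("<affinity> %d partitions, off-diagonal C in [%.3g, %.3g]\n",
              nrow(x$C), min(x$C, na.rm = TRUE), max(x$C, na.rm = TRUE)))
  invisible(x)
}

#' High-affinity partition pairs
#'
#' @param aff an [affinity_matrix()] result.
#' @param threshold affinity cutoff; 2 is used for network figures, 3 for
#'   tabulated pairs.
#' @return data frame of unordered pairs with `C > threshold`.
#' @export
high_affinity_pairs <- function(aff, threshold = 2) {
  idx <- which(upper.tri(aff$C) & aff$C > threshold, arr.ind = TRUE)
  df <- data.frame(a = idx[, 1], b = idx[, 2], C = aff$C[idx])
  df[order(-df$C), ]
}

#' Export an interaction edge list
#'
#' Plain-text edge list (optionally with layers and affinities) for
#' external graph viewers.
#'
#' @param pairs data frame from [classify_layers()] (optionally merged
#'   with affinities).
#' @param path output path.
#' @param keep_layers layers to keep (default scaffold and layer 1).
#' @export
write_edge_list <- function(pairs, path, keep_layers = c("scaffold", "1")) {
  df <- pairs[pairs$layer %in% keep_layers, , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Connected components of the significant-interaction graph
#'
#' Major-cluster extraction: nodes are partitions, edges are the pairs in
#' the kept layers; returns the component membership of every partition.
#'
#' @param pairs data frame from [classify_layers()].
#' @param n_nodes number of partitions.
#' @param keep_layers layers defining significance (default scaffold + 1).
#' @return integer vector of component ids, 1 = largest component.
#' @export
interaction_components <- function(pairs, n_nodes,
                                   keep_layers = c("scaffold", "1")) {
  keep <- pairs$layer %in% keep_layers
  pa <- as.integer(pairs$a); pb <- as.integer(pairs$b)
  comp <- seq_len(n_nodes)                 # union-find with path halving
  find <- function(x) { while (comp[x] != x) { comp[x] <<- comp[comp[x]]; x <- comp[x] }; x }
  for (e in which(keep)) {
    ra <- find(pa[e]); rb <- find(pb[e])
    if (ra != rb) comp[ra] <- rb
  }
  roots <- vapply(seq_len(n_nodes), find, integer(1))
  sizes <- table(roots)
  ord <- order(-as.integer(sizes))
  match(as.character(roots), names(sizes)[ord])
}
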