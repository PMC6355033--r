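#' Metastability index of a hub set
#'
#' For a candidate hub set `M`, the index is the ratio of the worst
#' hub-to-hub connection probability to the worst hit-any-hub probability:
#' `rho_M = max_{i in M} max_{j in M\\{i}} Gamma_ij /
#'          min_{i not in M} max_{j in M} Gamma_ij`.
#' In a metastable chain a probe leaving a hub returns to it before
#' reaching another hub (small numerator) while a probe leaving any
#' non-hub locus quickly reaches some hub (denominator near 1), so low
#' `rho_M` marks a hub set that captures the modular structure.
#'
#' @param gamma pairwise-committor matrix (see [pair_committor_matrix()]).
#' @param M integer vector of hub state indices, `2 <= |M| < n`.
#' @return the index value (> 0).
#' @export
metastability_index <- function(gamma, M) {
  n <- nrow(gamma)
  M <- as.integer(M)
  if (anyDuplicated(M) || any(M < 1) || any(M > n))
    stop("invalid hub set: indices out of range or duplicated")
  if (length(M) < 2) stop("invalid hub set: need at least 2 hubs")
  if (length(M) >= n) stop("invalid hub set: at least one non-hub must exist")
  num <- max(gamma[M, M], na.rm = TRUE)        # diagonal is NA
  GnM <- gamma[-M, M, drop = FALSE]
  den <- min(GnM[cbind(seq_len(nrow(GnM)), max.col(GnM, "first"))])
  num / den
}

#' Putative seed pair of hubs
#'
#' The first trial hub set: `a` is the locus with the highest stationary
#' weight (the densest attractor) and `b` minimizes the pair index
#' `rho_{a,b}`, i.e. the locus kinetically best separated from `a`. Ties
#' broken by lowest index.
#'
#' @param model a [chrom_msm()].
#' @param gamma pairwise-committor matrix.
#' @return list with `members` (the pair), `rho`, `beta`.
#' @export
seed_pair <- function(model, gamma) {
  n <- model$n_states
  if (n < 3) stop("need at least 3 states to seed a hub pair")
  a <- which.max(model$stationary)             # lowest index on ties
  cand <- setdiff(seq_len(n), a)
  rhos <- vapply(cand, function(b) metastability_index(gamma, c(a, b)),
                 numeric(1))
  b <- cand[which.min(rhos)]
  list(members = sort(c(a, b)), rho = min(rhos), beta = model$beta)
}

#' Monte-Carlo optimization of a hub set
#'
#' Metropolis search for the size-`n` hub set with the lowest
#' metastability index. Each iteration draws one of two move types with
#' equal probability: (a) replace a random hub `a` with
#' `argmax_i Gamma_ai`, its most reachable partner; (b) replace a random
#' hub with a uniformly random non-hub locus. Moves that would duplicate a
#' locus are rejected and redrawn. A trial set is accepted when its index
#' does not increase, or with probability `exp(-delta_rho / t_mc)`
#' otherwise. The best set ever visited is returned, so the result never
#' scores worse than the initial set.
#'
#' @param gamma pairwise-committor matrix.
#' @param M integer vector, initial hub set of the target size.
#' @param iters Monte-Carlo iterations (default 500).
#' @param t_mc Metropolis acceptance temperature on the rho scale
#'   (default 0.05).
#' @param max_redraws rejected-duplicate redraws allowed per iteration.
#' @return list with `members` (sorted), `rho`, plus counters `accepted`
#'   and `rejected_duplicates`.
#' @export
mc_optimize_hubs <- function(gamma, M, iters = 500, t_mc = 0.05,
                             max_redraws = 20) {
  n <- nrow(gamma)
  M <- as.integer(M)
  if (length(M) < 2 || length(M) >= n) stop("hub-set size out of range")
  if (iters < 1) stop("iters must be >= 1")
  gmax <- max.col(replace(gamma, is.na(gamma), -Inf), "first") # argmax_j Gamma_ij
  cur <- M
  cur_rho <- metastability_index(gamma, cur)
  best <- cur; best_rho <- cur_rho
  accepted <- 0L; dup_rejected <- 0L
  for (it in seq_len(iters)) {
    trial <- NULL
    for (try in seq_len(max_redraws)) {
      pos <- sample.int(length(cur), 1)
      repl <- if (stats::runif(1) < 0.5) {
        gmax[cur[pos]]                          # move (a): kinetic partner
      } else {
        nonhub <- seq_len(n)[-cur]
        nonhub[sample.int(length(nonhub), 1)]   # move (b): random non-hub
      }
      cand <- cur
      cand[pos] <- repl
      if (anyDuplicated(cand) == 0) { trial <- cand; break }
      dup_rejected <- dup_rejected + 1L
    }
    if (is.null(trial)) next
    trial_rho <- metastability_index(gamma, trial)
    d <- trial_rho - cur_rho
    if (d <= 0 || stats::runif(1) < exp(-d / t_mc)) {
      cur <- trial; cur_rho <- trial_rho
      accepted <- accepted + 1L
      if (cur_rho < best_rho) { best <- cur; best_rho <- cur_rho }
    }
  }
  list(members = sort(best), rho = best_rho, accepted = accepted,
       rejected_duplicates = dup_rejected)
}

#' Metastability-index profile over hub-set sizes
#'
#' Builds the profile `rho_M(n)` for `n = 2 .. n_max`: the size-2 set is
#' seeded from the stationary maximum (see [seed_pair()]) and optimized;
#' each subsequent size grows the previous optimum by the non-hub locus
#' whose addition gives the lowest index (greedy), then re-optimizes by
#' Monte Carlo. Local minima of the profile below the operational
#' threshold mark the natural levels of hierarchy.
#'
#' @param model a [chrom_msm()].
#' @param gamma pairwise-committor matrix; computed from the model when
#'   missing.
#' @param n_max largest hub-set size scanned (default 50).
#' @param iters Monte-Carlo iterations per size (default 500).
#' @param seed integer seed; per-size streams are derived
#'   deterministically from it.
#' @param t_mc Metropolis temperature, see [mc_optimize_hubs()].
#' @return object of class `rho_profile`: data frame-like list with
#'   `sizes`, `rho` (vector over sizes), `hubs` (list of member vectors),
#'   `beta`.
#' @export
rho_profile <- function(model, gamma = NULL, n_max = 50, iters = 500,
                        seed = 1L, t_mc = 0.05) {
  if (is.null(gamma)) gamma <- kinetics(model)$gamma
  if (n_max >= model$n_states) stop("n_max must be below the number of states")
  if (n_max < 2) stop("n_max must be >= 2")
  sizes <- 2:n_max
  rho <- numeric(length(sizes))
  hubs <- vector("list", length(sizes))
  set.seed(seed)
  init <- seed_pair(model, gamma)$members
  for (k in seq_along(sizes)) {
    n <- sizes[k]
    set.seed(seed + 7919L * n)           # deterministic per-size stream
    if (n > 2) {
      prev <- hubs[[k - 1]]
      cand <- seq_len(model$n_states)[-prev]
      add_rho <- vapply(cand, function(i)
        metastability_index(gamma, c(prev, i)), numeric(1))
      init <- c(prev, cand[which.min(add_rho)])
    }
    opt <- mc_optimize_hubs(gamma, init, iters = iters, t_mc = t_mc)
    rho[k] <- opt$rho
    hubs[[k]] <- opt$members
  }
  structure(list(sizes = sizes, rho = rho, hubs = hubs, beta = model$beta,
                 n_max = n_max, seed = seed),
            class = "rho_profile")
}

#' @export
print.rho_profile <- function(x, ...) {
  mins <- local_minima(x$rho)
  cat(sprintf("<rho_profile> sizes %d..%d at beta = %g\n",
              min(x$sizes), max(x$sizes), x$beta))
  cat(sprintf("  local minima at n = {%s}\n",
              paste(x$sizes[mins], collapse = ", ")))
  invisible(x)
}

#' @export
plot.rho_profile <- function(x, ...) {
  graphics::plot(x$sizes, x$rho, type = "b", pch = 16,
                 xlab = "hub-set size n", ylab = expression(rho[M]), ...)
  mins <- local_minima(x$rho)
  graphics::points(x$sizes[mins], x$rho[mins], col = 2, pch = 1, cex = 2)
  invisible(x)
}

# strict local minima; plateaus take the smallest n; endpoints count when
# strictly below their single neighbour
local_minima <- function(rho) {
  k <- length(rho)
  if (k == 1) return(1L)
  left <- c(TRUE, rho[-1] < rho[-k])             # strictly below left value
  right <- c(rho[-k] <= rho[-1], TRUE)           # not above right value
  which(left & right)
}

#' Select hierarchy levels from a profile
#'
#' Keeps local minima of `rho(n)` that mark a genuine separation of
#' kinetic scales, drops the trivial size-2 level unless `keep_trivial`,
#' and applies the ascending growth rule `n_i >= min_growth * n_{i-1}` so
#' that consecutive levels are genuinely different scales.
#'
#' A minimum qualifies when its index is below `rho_threshold` both in
#' absolute terms and relative to the lower of its flanking profile
#' maxima. On profiles whose baseline hovers near 1 (real chromosomes)
#' the relative condition is vacuous and the rule is the plain
#' `rho < rho_threshold` cutoff; it additionally discards shallow
#' near-degenerate dips (e.g. a minimum at 0.5 flanked by 0.55) that an
#' exhaustive hub search can expose between true levels, which reflect
#' alternative hub placements of comparable quality rather than a
#' separated time scale.
#'
#' @param profile a [rho_profile()].
#' @param rho_threshold cutoff on the index, absolute and relative to the
#'   flanking maxima (default 0.8).
#' @param min_growth required size ratio between consecutive levels
#'   (default 2).
#' @param keep_trivial keep the size-2 level (used for the toy model,
#'   where the top split is meaningful; on real chromosomes size 2 merely
#'   finds the two arms).
#' @param skip_first drop the smallest qualifying level before applying
#'   the growth rule (per-chromosome override used for the largest
#'   chromosomes, where the first minimum gives partitions that are too
#'   large).
#' @return object of class `hierarchy_levels`: list with `sizes`, `hubs`
#'   (hub sets at the selected sizes), `rho` values, and the parameters.
#' @export
select_hierarchy <- function(profile, rho_threshold = 0.8, min_growth = 2,
                             keep_trivial = FALSE, skip_first = FALSE) {
  mins <- local_minima(profile$rho)
  sizes <- profile$sizes[mins]
  rhos <- profile$rho[mins]
  flank <- vapply(seq_along(mins), function(k) {
    lo <- if (k == 1) 1L else mins[k - 1] + 1L
    hi <- if (k == length(mins)) length(profile$rho) else mins[k + 1] - 1L
    seg <- setdiff(lo:hi, mins[k])
    if (length(seg) == 0) 0 else {
      left <- seg[seg < mins[k]]; right <- seg[seg > mins[k]]
      min(if (length(left)) max(profile$rho[left]) else Inf,
          if (length(right)) max(profile$rho[right]) else Inf)
    }
  }, numeric(1))
  ok <- rhos < rho_threshold * pmin(1, flank)
  sizes <- sizes[ok]; rhos <- rhos[ok]
  if (!keep_trivial) { keep <- sizes != 2; sizes <- sizes[keep]; rhos <- rhos[keep] }
  if (skip_first && length(sizes) > 1) { sizes <- sizes[-1]; rhos <- rhos[-1] }
  sel <- logical(length(sizes))
  last <- -Inf
  for (k in seq_along(sizes)) {
    if (sizes[k] >= min_growth * last || !any(sel)) {
      sel[k] <- TRUE
      last <- sizes[k]
    }
  }
  sizes <- sizes[sel]; rhos <- rhos[sel]
  structure(list(sizes = sizes, rho = rhos,
                 hubs = profile$hubs[match(sizes, profile$sizes)],
                 rho_threshold = rho_threshold, min_growth = min_growth,
                 beta = profile$beta),
            class = "hierarchy_levels")
}

#' @export
print.hierarchy_levels <- function(x, ...) {
  cat(sprintf("<hierarchy_levels> %d level(s): {%s} (rho < %g)\n",
              length(x$sizes), paste(x$sizes, collapse = ", "),
              x$rho_threshold))
  invisible(x)
}

#' Write a metastability profile as TSV
#' @param profile a [rho_profile()].
#' @param path output path.
#' @export
write_rho_profile <- function(profile, path) {
  df <- data.frame(n = profile$sizes, rho = profile$rho,
                   hubs = vapply(profile$hubs, paste, "", collapse = ","))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
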