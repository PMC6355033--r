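#' Specification of the hierarchical toy chromosome
#'
#' The toy chromosome is a 1D lattice of loci whose intrinsic energies
#' follow a nested-basin profile: the chromosome splits into
#' `branching[1]` top-level basins separated by the tallest barriers, each
#' recursively subdivided per `branching`, down to the leaf wells. The
#' default reproduces a three-level landscape: 2 x 3 x 3 = 18 leaf wells,
#' barriers of 2, 1.25 and 0.5 energy units (tallest at the top level), 500
#' loci, and a power-law contact probability `(d0/d_ij)^alpha` with
#' `alpha = 1.5` between non-adjacent loci.
#'
#' @param n_loci number of loci (default 500).
#' @param branching integer vector, number of children per level
#'   (default `c(2, 3, 3)`); every element must be >= 2.
#' @param barrier_heights barrier height per level in dimensionless energy
#'   units, strictly decreasing (default `c(2, 1.25, 0.5)`).
#' @param well_shape `"cosine"` (default) or `"parabolic"` interpolation
#'   between well bottoms and barrier tops.
#' @param alpha contact-probability decay exponent (default 1.5).
#' @param d0 adjacent-locus distance in locus units (1).
#' @param seed kept for interface uniformity; the generator is
#'   deterministic and ignores it.
#' @return an object of class `toy_spec`.
#' @export
toy_spec <- function(n_loci = 500L, branching = c(2L, 3L, 3L),
                     barrier_heights = c(2, 1.25, 0.5),
                     well_shape = c("cosine", "parabolic"),
                     alpha = 1.5, d0 = 1, seed = 1L) {
  well_shape <- match.arg(well_shape)
  branching <- as.integer(branching)
  if (length(branching) < 1 || any(branching < 2))
    stop("every branching element must be >= 2")
  if (length(barrier_heights) != length(branching))
    stop("barrier_heights must have one entry per level")
  if (length(barrier_heights) > 1 && any(diff(barrier_heights) >= 0))
    stop("barrier_heights must be strictly decreasing with level")
  if (alpha < 0) stop("alpha must be >= 0")
  n_wells <- prod(branching)
  if (n_loci < n_wells) stop("n_loci too small to host all wells")
  structure(list(n_loci = as.integer(n_loci), branching = branching,
                 barrier_heights = as.numeric(barrier_heights),
                 well_shape = well_shape, alpha = alpha, d0 = d0,
                 seed = as.integer(seed)),
            class = "toy_spec")
}

#' Generate the hierarchical 1D energy profile
#'
#' Loci are assigned to leaf wells in contiguous equal-length blocks
#' (remainder appended to the last well). Each internal well boundary
#' carries a barrier whose height is set by the shallowest hierarchy level
#' separating the two wells; well bottoms sit at energy 0 and the profile
#' interpolates smoothly (half-cosine by default) between bottoms and
#' barrier tops. Ground-truth basin labels are recorded per level.
#'
#' @param spec a [toy_spec()].
#' @return object of class `toy_profile`: list with `energy` (numeric,
#'   length `n_loci`), `basin_labels` (matrix, one column per level), and
#'   the generating `spec`.
#' @export
toy_profile <- function(spec = toy_spec()) {
  stopifnot(inherits(spec, "toy_spec"))
  L <- length(spec$branching)
  n_wells <- prod(spec$branching)
  n <- spec$n_loci
  base <- n %/% n_wells
  sizes <- rep(base, n_wells)
  sizes[n_wells] <- sizes[n_wells] + n %% n_wells
  ends <- cumsum(sizes)                  # last locus index (1-based) per well
  starts <- c(1, utils::head(ends, -1) + 1)

  # per-level label of each leaf well; level l groups leaves in blocks
  leaf_labels <- sapply(seq_len(L), function(l) {
    per <- prod(spec$branching[seq_len(l)])
    rep(seq_len(per), each = n_wells / per)
  })
  if (L == 1) leaf_labels <- matrix(leaf_labels, ncol = 1)

  # barrier height between adjacent wells w, w+1: set by the highest level
  # at which their labels differ (level 1 = tallest barrier)
  barrier_h <- vapply(seq_len(n_wells - 1), function(w) {
    lvl <- which(leaf_labels[w, ] != leaf_labels[w + 1, ])[1]
    spec$barrier_heights[lvl]
  }, numeric(1))

  centers <- floor((starts + ends) / 2)
  tops <- ends[-n_wells]                 # barrier sits on last locus of well
  shape <- function(t) {                 # t in [0,1], 0 at bottom, 1 at top
    if (spec$well_shape == "cosine") (1 - cos(pi * t)) / 2 else t^2
  }
  E <- numeric(n)
  for (w in seq_len(n_wells)) {
    c_w <- centers[w]
    if (w > 1) {                         # rising flank from previous barrier
      t_prev <- tops[w - 1]
      idx <- (t_prev + 1):c_w
      if (length(idx) > 0 && c_w > t_prev)
        E[idx] <- barrier_h[w - 1] * shape((c_w - idx) / (c_w - t_prev))
    }
    if (w < n_wells) {                   # rising flank towards next barrier
      t_w <- tops[w]
      if (t_w > c_w) {
        idx <- c_w:t_w
        E[idx] <- pmax(E[idx], barrier_h[w] * shape((idx - c_w) / (t_w - c_w)))
      } else E[t_w] <- max(E[t_w], barrier_h[w])   # degenerate one-locus well
    }
  }
  labels <- leaf_labels[rep(seq_len(n_wells), sizes), , drop = FALSE]
  colnames(labels) <- paste0("level", seq_len(L))
  structure(list(energy = E, basin_labels = labels, spec = spec,
                 well_starts = starts, well_ends = ends,
                 well_centers = centers),
            class = "toy_profile")
}

#' @export
print.toy_profile <- function(x, ...) {
  cat(sprintf("<toy_profile> %d loci, %d leaf wells, %d levels (branching %s)\n",
              length(x$energy), prod(x$spec$branching),
              length(x$spec$branching),
              paste(x$spec$branching, collapse = "/")))
  invisible(x)
}

#' Pairwise contact energies of the toy chromosome
#'
#' `E_ij = (E_i + E_j)/2 - alpha * ln(d0/d_ij)` with `d_ij = |i - j| * d0`,
#' so adjacent loci interact at the mean of their intrinsic energies and
#' more distant pairs are penalized by the power-law contact probability.
#' The diagonal is set to `Inf` (self-contacts excluded).
#'
#' @param profile a [toy_profile()].
#' @param alpha contact exponent; defaults to the profile's spec.
#' @param d0 adjacent-locus distance; defaults to the profile's spec.
#' @return symmetric numeric matrix of pair energies.
#' @export
toy_pair_energy <- function(profile, alpha = profile$spec$alpha,
                            d0 = profile$spec$d0) {
  if (alpha < 0) stop("alpha must be >= 0")
  E <- profile$energy
  n <- length(E)
  d <- abs(outer(seq_len(n), seq_len(n), "-")) * d0
  Ep <- outer(E, E, "+") / 2 + alpha * log(d / d0)
  diag(Ep) <- Inf
  Ep
}

#' Markov state model of the toy chromosome
#'
#' Builds the Boltzmann-flux MSM at inverse temperature `beta` from the toy
#' pair energies: flux `pi_ij` proportional to `exp(-beta * E_ij)` over
#' ordered off-diagonal pairs, stationary weights `mu_i = sum_j pi_ij`, and
#' row-stochastic transitions `p_ij = pi_ij / mu_i` (zero diagonal). The
#' construction satisfies detailed balance by symmetry of the flux.
#'
#' @param profile a [toy_profile()].
#' @param beta inverse temperature, > 0.
#' @param alpha,d0 contact-model parameters; default to the profile's spec.
#' @return a [chrom_msm()] object.
#' @export
toy_msm <- function(profile, beta, alpha = profile$spec$alpha,
                    d0 = profile$spec$d0) {
  if (length(profile$energy) < 2) stop("need at least 2 loci")
  Ep <- toy_pair_energy(profile, alpha = alpha, d0 = d0)
  build_msm(energy_landscape(E_pair = Ep), beta = beta)
}

#' Convert the toy chromosome to pseudo Hi-C counts
#'
#' Emits counts `f_ij = exp(-E_ij)` on a pseudo-chromosome so the toy model
#' can be piped through the same reading/smoothing/masking machinery as
#' real data. At `beta = 1` the MSM built from these counts is identical to
#' [toy_msm()].
#'
#' @param profile a [toy_profile()].
#' @param resolution bin width in bp for the pseudo-chromosome.
#' @param chrom pseudo-chromosome name.
#' @param scale multiplicative factor applied to the counts.
#' @return a [contact_matrix()].
#' @export
toy_contacts <- function(profile, resolution = 50000, chrom = "toy",
                         scale = 1) {
  f <- exp(-toy_pair_energy(profile)) * scale
  diag(f) <- 0
  contact_matrix(f, chrom = chrom, resolution = resolution)
}

#' Export profile and ground truth as TSV
#' @param profile a [toy_profile()].
#' @param path output path.
#' @export
write_toy_profile <- function(profile, path) {
  df <- data.frame(locus_index = seq_along(profile$energy) - 1L,
                   E = profile$energy)
  df <- cbind(df, as.data.frame(profile$basin_labels))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a toy-landscape spec from a key=value config file
#' @param path config path with keys matching [toy_spec()] arguments;
#'   vector values comma-separated.
#' @export
read_toy_spec <- function(path) {
  kv <- read_config(path)
  args <- list()
  if (!is.null(kv$n_loci)) args$n_loci <- as.integer(kv$n_loci)
  if (!is.null(kv$branching))
    args$branching <- as.integer(strsplit(kv$branching, ",")[[1]])
  if (!is.null(kv$barrier_heights))
    args$barrier_heights <- as.numeric(strsplit(kv$barrier_heights, ",")[[1]])
  if (!is.null(kv$well_shape)) args$well_shape <- kv$well_shape
  if (!is.null(kv$alpha)) args$alpha <- as.numeric(kv$alpha)
  if (!is.null(kv$d0)) args$d0 <- as.numeric(kv$d0)
  if (!is.null(kv$seed)) args$seed <- as.integer(kv$seed)
  do.call(toy_spec, args)
}
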