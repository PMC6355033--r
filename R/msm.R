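#' Contact-energy landscape
#'
#' Pairwise contact energies `E_ij = -ln f_ij` and per-locus energies
#' `E_i = -ln f_i`, `f_i = sum_j f_ij`: the more often two loci are found
#' in contact, the lower (more stable) their pair energy. Pairs with zero
#' counts get infinite energy, i.e. zero flux at any temperature.
#'
#' @param E_pair symmetric matrix of pair energies (`Inf` allowed; the
#'   diagonal is forced to `Inf` — self-contacts carry no flux).
#' @param E_locus optional per-locus energies; recomputed from `E_pair`
#'   when missing.
#' @return object of class `energy_landscape`.
#' @export
energy_landscape <- function(E_pair, E_locus = NULL) {
  E_pair <- as.matrix(E_pair)
  fin <- is.finite(E_pair)
  if (max(abs(E_pair[fin & t(fin)] - t(E_pair)[fin & t(fin)])) > 1e-8)
    stop("E_pair must be symmetric")
  diag(E_pair) <- Inf
  if (is.null(E_locus)) {
    f <- exp(-E_pair)
    f[!is.finite(E_pair)] <- 0
    E_locus <- -log(rowSums(f))
  }
  structure(list(E_pair = E_pair, E_locus = E_locus,
                 infinite_pairs = !is.finite(E_pair)),
            class = "energy_landscape")
}

#' Energies from a contact matrix
#'
#' @param cm a masked [contact_matrix()] (all row sums positive).
#' @param exclude_diagonal drop self-contacts from `f_i = sum_j f_ij`
#'   (default TRUE; self-pairs never enter the Markov model).
#' @return an [energy_landscape()].
#' @export
pair_energies <- function(cm, exclude_diagonal = TRUE) {
  f <- cm$counts
  if (exclude_diagonal) diag(f) <- 0
  if (any(rowSums(f) <= 0))
    stop("contact matrix has inactive loci; run mask_inactive_loci() first")
  E_pair <- -log(f)
  energy_landscape(E_pair, E_locus = -log(rowSums(f)))
}

#' Boltzmann-flux Markov state model
#'
#' Builds the discrete-time Markov state model of a probe walking the
#' contact-energy landscape at inverse temperature `beta`:
#' flux `pi_ij = exp(-beta E_ij) / Z(beta)` with the partition function
#' `Z` summed over ordered off-diagonal pairs, stationary weights
#' `mu_i = sum_j pi_ij`, and transition probabilities
#' `p_ij = pi_ij / mu_i` with zero diagonal. Detailed balance
#' `mu_i p_ij = mu_j p_ji` holds by symmetry of the flux. Weights are
#' exponentiated after a max-shift so high `beta` does not underflow the
#' dominant contacts.
#'
#' @param E an [energy_landscape()] (or a [contact_matrix()], converted via
#'   [pair_energies()]).
#' @param beta inverse temperature, > 0. Low beta lets all contacts
#'   contribute; annealing (high beta) concentrates the walk on the
#'   strongest contacts and exposes metastability.
#' @return object of class `chrom_msm` with elements `flux`, `stationary`,
#'   `transition`, `beta`, `n_states`.
#' @export
chrom_msm <- function(E, beta = 1) {
  if (inherits(E, "contact_matrix")) E <- pair_energies(E)
  build_msm(E, beta)
}

#' @rdname chrom_msm
#' @param require_connected error when the positive-flux graph is
#'   disconnected (default TRUE; first-passage times would diverge). The
#'   genome-wide mean-field path disables this, since block sums remain
#'   well defined on a disconnected flux graph.
#' @export
build_msm <- function(E, beta, require_connected = TRUE) {
  stopifnot(inherits(E, "energy_landscape"))
  if (beta <= 0) stop("beta must be > 0")
  n <- nrow(E$E_pair)
  if (n < 2) stop("need at least 2 loci")
  A <- -beta * E$E_pair              # log-space weights; -Inf where no pair
  shift <- max(A[is.finite(A)])
  W <- exp(A - shift)
  W[!is.finite(A)] <- 0
  if (any(rowSums(W) == 0))
    stop("some loci have no finite-energy pair at this beta")
  if (require_connected && !flux_connected(W))
    stop("flux graph is disconnected at beta = ", beta)
  Z <- sum(W)
  flux <- W / Z
  mu <- rowSums(flux)
  p <- flux / mu
  structure(list(flux = flux, stationary = mu, transition = p,
                 beta = beta, n_states = n),
            class = "chrom_msm")
}

# breadth-first connectivity of the positive-flux graph
flux_connected <- function(W) {
  n <- nrow(W)
  seen <- logical(n)
  frontier <- 1L
  seen[1L] <- TRUE
  while (length(frontier) > 0) {
    nxt <- which(colSums(W[frontier, , drop = FALSE] > 0) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

#' @export
print.chrom_msm <- function(x, ...) {
  cat(sprintf("<chrom_msm> %d states, beta = %g\n", x$n_states, x$beta))
  invisible(x)
}

#' @export
summary.chrom_msm <- function(object, ...) {
  mu <- object$stationary
  db <- max(abs(object$flux - t(object$flux)))
  cat(sprintf("<chrom_msm> %d states, beta = %g\n", object$n_states,
              object$beta))
  cat(sprintf("  sum(mu) = %.12f, max row-sum deviation = %.2e\n",
              sum(mu), max(abs(rowSums(object$transition) - 1))))
  cat(sprintf("  detailed-balance (flux asymmetry) = %.2e\n", db))
  cat(sprintf("  mu range: [%.3e, %.3e], argmax = %d\n",
              min(mu), max(mu), which.max(mu)))
  invisible(object)
}

#' Simulate the random walk of a probe
#'
#' Samples discrete-time trajectories of the Markov chain; useful for
#' illustrating metastable trapping at high beta.
#'
#' @param object a [chrom_msm()].
#' @param nsim number of steps per trajectory.
#' @param seed optional RNG seed.
#' @param n_walkers number of independent trajectories.
#' @param start starting state(s), recycled across walkers; default sampled
#'   from the stationary distribution.
#' @param ... unused.
#' @return integer matrix `nsim x n_walkers` of visited states.
#' @export
simulate.chrom_msm <- function(object, nsim = 1000, seed = NULL,
                               n_walkers = 1, start = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  P <- object$transition
  cum <- t(apply(P, 1, cumsum))
  if (is.null(start))
    start <- sample.int(object$n_states, n_walkers, replace = TRUE,
                        prob = object$stationary)
  state <- rep_len(as.integer(start), n_walkers)
  out <- matrix(0L, nsim, n_walkers)
  for (s in seq_len(nsim)) {
    u <- stats::runif(n_walkers)
    state <- vapply(seq_len(n_walkers),
                    function(w) findInterval(u[w], cum[state[w], ]) + 1L,
                    integer(1))
    out[s, ] <- state
  }
  out
}

#' Mean first-passage times
#'
#' For every target state `j`, the first-passage times from all other
#' states solve the linear system `tau_ij = 1 + sum_{k != j} p_ik tau_kj`,
#' solved here as a dense system per target column. A singular or
#' ill-conditioned solve (the symptom of an effectively disconnected chain
#' at too-high beta) raises a condition of class `chromsm_singular`
#' carrying the offending beta.
#'
#' @param model a [chrom_msm()].
#' @param residual_tol maximum allowed residual `max|A tau - 1|`.
#' @return matrix `tau` of MFPTs in steps; the diagonal is 0 (the mean
#'   recurrence time is a separate quantity, see [mean_recurrence()]).
#' @export
mean_first_passage <- function(model, residual_tol = 1e-6) {
  P <- model$transition
  n <- nrow(P)
  tau <- matrix(0, n, n)
  ones <- rep(1, n - 1)
  for (j in seq_len(n)) {
    idx <- seq_len(n)[-j]
    A <- -P[idx, idx, drop = FALSE]
    diag(A) <- diag(A) + 1
    t_j <- tryCatch(solve(A, ones), error = function(e) NULL)
    bad <- is.null(t_j) || any(!is.finite(t_j)) || any(t_j <= 0) ||
      max(abs(A %*% t_j - ones)) > residual_tol * max(1, max(abs(t_j)))
    if (bad) {
      cond <- structure(class = c("chromsm_singular", "error", "condition"),
                        list(message = sprintf(
                          "singular MFPT solve for target %d at beta = %g",
                          j, model$beta), call = sys.call(-1),
                          beta = model$beta, target = j))
      stop(cond)
    }
    tau[idx, j] <- t_j
  }
  tau
}

#' Mean recurrence times
#'
#' `tau_i = 1 + sum_{k != i} p_ik tau_ki`: the mean number of steps for a
#' walker leaving `i` to first return to `i`. For an ergodic chain this
#' equals `1/mu_i` (Kac's formula), which serves as an internal
#' consistency check of the first-passage solves.
#'
#' @param model a [chrom_msm()].
#' @param mfpt MFPT matrix from [mean_first_passage()].
#' @return numeric vector of recurrence times in steps.
#' @export
mean_recurrence <- function(model, mfpt) {
  1 + rowSums(model$transition * t(mfpt))
}

#' Pairwise committor matrix
#'
#' `Gamma_ij = tau_i / (tau_ij + tau_ji)` is the probability that a probe
#' departing from locus `i` hits locus `j` before returning to `i`. Values
#' lie in (0, 1]; symmetry is not guaranteed (it requires `mu_i = mu_j`).
#'
#' @param mfpt MFPT matrix.
#' @param mrt mean recurrence-time vector.
#' @return matrix `Gamma` with `NA` diagonal.
#' @export
pair_committor_matrix <- function(mfpt, mrt) {
  denom <- mfpt + t(mfpt)
  diag(denom) <- NA_real_
  if (any(denom[!is.na(denom)] <= 0)) stop("non-positive tau_ij + tau_ji")
  g <- mrt / denom
  diag(g) <- NA_real_
  g
}

#' Kinetic matrices of a model
#'
#' Convenience wrapper computing MFPT, MRT and the pairwise committor in
#' one pass.
#'
#' @param model a [chrom_msm()].
#' @return list with `mfpt`, `mrt`, `gamma`.
#' @export
kinetics <- function(model) {
  tau <- mean_first_passage(model)
  mrt <- mean_recurrence(model, tau)
  list(mfpt = tau, mrt = mrt, gamma = pair_committor_matrix(tau, mrt))
}

#' Annealing-parameter selection
#'
#' Scans candidate integer inverse temperatures from the largest down and
#' returns the highest one at which the model builds, stays connected, and
#' every first-passage solve is finite, positive and within the residual
#' tolerance. Annealing as far as the numerics allow maximizes the
#' separation of time scales exploited by the metastability analysis.
#'
#' @param E an [energy_landscape()].
#' @param candidates ascending integer candidates (default 1:12).
#' @param residual_tol forwarded to [mean_first_passage()].
#' @return the selected beta, with attribute `"rejected"` listing the
#'   candidates that failed (largest first).
#' @export
select_beta <- function(E, candidates = 1:12, residual_tol = 1e-6) {
  if (length(candidates) == 0) stop("no beta candidates supplied")
  candidates <- sort(candidates)
  rejected <- integer(0)
  for (beta in rev(candidates)) {
    ok <- tryCatch({
      m <- build_msm(E, beta)
      invisible(mean_first_passage(m, residual_tol))
      TRUE
    }, error = function(e) FALSE)
    if (ok) {
      attr(beta, "rejected") <- rejected
      return(beta)
    }
    rejected <- c(rejected, beta)
  }
  stop("no candidate beta passed the first-passage stability check")
}

#' Write a square matrix as TSV
#' @param m matrix.
#' @param path output path.
#' @export
write_matrix_tsv <- function(m, path) {
  utils::write.table(m, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
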