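#' Committor probabilities (soft partitions)
#'
#' For each hub `a` in the hub set `M`, `q_a(i)` is the probability that a
#' probe departing locus `i` reaches `a` before any other hub. Interior
#' loci solve the harmonic system `sum_j (p_ij - delta_ij) q_a(j) = 0`
#' with boundary conditions `q_a(a) = 1`, `q_a(b) = 0` for the other hubs.
#' The interior matrix is factored once and shared across hubs. By the
#' partition of unity, each row of the committor matrix sums to 1, so
#' `q_a(i)` is read as the degree of membership of locus `i` in the soft
#' partition around hub `a`.
#'
#' @param model a [chrom_msm()].
#' @param hubs integer vector of hub state indices (or a list with a
#'   `members` element, as returned by the optimizers).
#' @return object of class `soft_partition`: list with `q` (matrix, rows =
#'   loci, columns = hubs), `hubs`.
#' @export
committor_probabilities <- function(model, hubs) {
  if (is.list(hubs)) hubs <- hubs$members
  hubs <- as.integer(hubs)
  n <- model$n_states
  if (anyDuplicated(hubs) || any(hubs < 1) || any(hubs > n) ||
      length(hubs) < 2)
    stop("invalid hub set")
  P <- model$transition
  interior <- seq_len(n)[-hubs]
  A <- -P[interior, interior, drop = FALSE]
  diag(A) <- diag(A) + 1
  B <- P[interior, hubs, drop = FALSE]
  X <- tryCatch(solve(A, B), error = function(e)
    stop(sprintf("singular committor system at beta = %g", model$beta)))
  q <- matrix(0, n, length(hubs))
  q[interior, ] <- X
  q[cbind(hubs, seq_along(hubs))] <- 1
  colnames(q) <- as.character(hubs)
  structure(list(q = q, hubs = hubs), class = "soft_partition")
}

#' @export
print.soft_partition <- function(x, ...) {
  cat(sprintf("<soft_partition> %d loci x %d hubs, max row-sum deviation %.2e\n",
              nrow(x$q), ncol(x$q), max(abs(rowSums(x$q) - 1))))
  invisible(x)
}

#' Hard partitions from committors
#'
#' Assigns every locus to the hub with the maximal committor probability
#' (`argmax_b q_b(i)`); ties go to the hub with the lower genomic index.
#' Partitions need not be genomically contiguous.
#'
#' @param soft a [committor_probabilities()] result.
#' @return object of class `hard_partition`: list with `assignment`
#'   (integer vector, values = partition numbers in genomic hub order),
#'   `hubs` (sorted), `k`.
#' @export
hard_assign <- function(soft) {
  ord <- order(soft$hubs)
  q <- soft$q[, ord, drop = FALSE]       # columns in genomic hub order
  a <- max.col(q, ties.method = "first") # ties -> lower hub index
  structure(list(assignment = a, hubs = soft$hubs[ord],
                 k = length(soft$hubs)),
            class = "hard_partition")
}

#' Construct a hard partition from an assignment vector
#' @param assignment integer vector of partition memberships (1..k).
#' @param hubs optional hub loci.
#' @export
hard_partition <- function(assignment, hubs = NULL) {
  assignment <- as.integer(assignment)
  structure(list(assignment = assignment, hubs = hubs,
                 k = length(unique(assignment))),
            class = "hard_partition")
}

#' @export
print.hard_partition <- function(x, ...) {
  cat(sprintf("<hard_partition> %d loci in %d partitions\n",
              length(x$assignment), x$k))
  invisible(x)
}

#' Genomic extents of a hard partition
#'
#' Runs of consecutive loci with the same assignment become intervals; a
#' partition may own several intervals.
#'
#' @param parts a [hard_partition()].
#' @param cm the [contact_matrix()] the model was built on (provides
#'   chromosome, resolution and bin starts); when omitted, locus indices
#'   are used as coordinates.
#' @return data frame with columns chrom, start, end, partition.
#' @export
partition_intervals <- function(parts, cm = NULL) {
  a <- parts$assignment
  r <- rle(a)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  if (is.null(cm)) {
    data.frame(chrom = "chr", start = starts - 1, end = ends,
               partition = r$values)
  } else {
    data.frame(chrom = cm$chrom, start = cm$bin_starts[starts],
               end = cm$bin_starts[ends] + cm$resolution,
               partition = r$values)
  }
}

#' Write a partition as BED
#' @param parts a [hard_partition()].
#' @param cm matching [contact_matrix()].
#' @param path output path.
#' @param level label written in the score column.
#' @export
write_partition_bed <- function(parts, cm, path, level = 1) {
  iv <- partition_intervals(parts, cm)
  df <- data.frame(iv$chrom,
                   format(iv$start, scientific = FALSE, trim = TRUE),
                   format(iv$end, scientific = FALSE, trim = TRUE),
                   iv$partition, level)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Hierarchical partition labels
#'
#' Names partitions across levels by nesting: top-level partitions are
#' numbered in genomic hub order ("1", "2", ...); each child partition is
#' assigned to the parent holding the majority of its loci and numbered
#' within that parent ("1.2", "1.2.4", ...).
#'
#' @param partition_list list of [hard_partition()]s, coarsest first.
#' @return list of character vectors, one per level, giving the label of
#'   each partition at that level.
#' @export
hierarchy_labels <- function(partition_list) {
  out <- vector("list", length(partition_list))
  out[[1]] <- as.character(seq_len(partition_list[[1]]$k))
  if (length(partition_list) > 1) {
    for (l in 2:length(partition_list)) {
      parent <- partition_list[[l - 1]]$assignment
      child <- partition_list[[l]]$assignment
      k <- partition_list[[l]]$k
      par_of <- vapply(seq_len(k), function(A) {
        tab <- table(parent[child == A])
        as.integer(names(tab)[which.max(tab)])
      }, integer(1))
      lab <- character(k)
      for (p in unique(par_of)) {
        kids <- which(par_of == p)
        # order children genomically by their first locus
        first <- vapply(kids, function(A) which(child == A)[1], integer(1))
        kids <- kids[order(first)]
        lab[kids] <- paste0(out[[l - 1]][p], ".", seq_along(kids))
      }
      out[[l]] <- lab
    }
  }
  out
}

#' Normalized mutual information between two partition schemes
#'
#' `I(P1,P2) = pref * sum_AB nu_AB ln(nu_AB / (nu_A nu_B))` where `nu` are
#' locus fractions. The default variant `"sym"` uses the symmetric
#' prefactor `2 / (H(P1) + H(P2))` so that identical schemes score exactly
#' 1; variant `"paper"` uses `1 / (H(P1) + H(P2))` (identical schemes then
#' score 0.5).
#'
#' @param P1,P2 [hard_partition()]s (or plain assignment vectors) over the
#'   same loci.
#' @param variant `"sym"` (default) or `"paper"`.
#' @return the NMI value.
#' @export
normalized_mutual_information <- function(P1, P2, variant = c("sym", "paper")) {
  variant <- match.arg(variant)
  a <- if (inherits(P1, "hard_partition")) P1$assignment else as.integer(P1)
  b <- if (inherits(P2, "hard_partition")) P2$assignment else as.integer(P2)
  if (length(a) != length(b)) stop("schemes cover different locus sets")
  n <- length(a)
  ka <- max(a); kb <- max(b)
  joint <- tabulate((b - 1L) * ka + a, nbins = ka * kb) / n
  nu_a <- tabulate(a, nbins = ka) / n
  nu_b <- tabulate(b, nbins = kb) / n
  H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  H1 <- H(nu_a); H2 <- H(nu_b)
  if (H1 == 0 || H2 == 0)
    stop("undefined entropy: a scheme has a single partition")
  jm <- matrix(joint, ka, kb)
  pos <- jm > 0
  I <- sum(jm[pos] * log(jm[pos] / outer(nu_a, nu_b)[pos]))
  pref <- if (variant == "sym") 2 else 1
  pref * I / (H1 + H2)
}

#' Rescaled mutual information
#'
#' Linear rescale of the NMI against the random-boundary baseline:
#' `RMI = (NMI - 0.77) / 0.23`, mapping the baseline mean to 0 and perfect
#' agreement to 1. Values outside \[0, 1\] are possible for extreme inputs
#' and are not clipped here.
#'
#' @param nmi NMI value(s).
#' @param baseline baseline mean NMI (default 0.77).
#' @export
rescaled_mi <- function(nmi, baseline = 0.77) {
  (nmi - baseline) / (1 - baseline)
}

#' Random-boundary NMI baseline
#'
#' Estimates the NMI expected between unrelated partition schemes of the
#' same granularity. The mutual information of two partition schemes is a
#' per-chromosome quantity: for each sample and each chromosome, two
#' schemes with the chromosome's partition count are generated by drawing
#' uniformly random distinct internal boundaries (partitions are
#' contiguous blocks) and compared by NMI; per-chromosome values are
#' combined into a genome value by a locus-weighted mean. Returns the
#' mean over samples.
#'
#' @param scheme either a [hard_partition()] (single chromosome) or a data
#'   frame with columns `n_loci` and `k` (one row per chromosome).
#' @param samples number of random scheme pairs.
#' @param seed RNG seed.
#' @param variant NMI variant, see [normalized_mutual_information()].
#' @param combine across chromosomes: `"weighted"` (by locus count,
#'   default), `"mean"` (unweighted), or `"pooled"` (concatenate loci and
#'   compute one NMI; inflated by the shared chromosome identity).
#' @return mean NMI, with attribute `"sd"` of the per-sample values.
#' @export
random_boundary_baseline <- function(scheme, samples = 100, seed = 1L,
                                     variant = "sym",
                                     combine = c("weighted", "mean",
                                                 "pooled")) {
  combine <- match.arg(combine)
  if (inherits(scheme, "hard_partition")) {
    df <- data.frame(n_loci = length(scheme$assignment), k = scheme$k)
  } else df <- as.data.frame(scheme)
  if (any(df$k < 1) || any(df$k > df$n_loci)) stop("invalid scheme counts")
  if (sum(df$k) < 2) stop("undefined entropy: fewer than 2 partitions")
  set.seed(seed)
  draw1 <- function(n, k) {
    cuts <- if (k > 1) sort(sample.int(n - 1L, k - 1L)) else integer(0)
    rep(seq_len(k), diff(c(0L, cuts, n)))
  }
  one_sample <- function() {
    if (combine == "pooled") {
      pool <- function() {
        offs <- 0L
        unlist(lapply(seq_len(nrow(df)), function(r) {
          p <- draw1(df$n_loci[r], df$k[r]) + offs
          offs <<- offs + df$k[r]
          p
        }))
      }
      return(normalized_mutual_information(pool(), pool(), variant = variant))
    }
    per <- vapply(seq_len(nrow(df)), function(r) {
      if (df$k[r] < 2) return(NA_real_)   # single-partition chromosome
      normalized_mutual_information(draw1(df$n_loci[r], df$k[r]),
                                    draw1(df$n_loci[r], df$k[r]),
                                    variant = variant)
    }, numeric(1))
    w <- if (combine == "weighted") df$n_loci else rep(1, nrow(df))
    stats::weighted.mean(per, w, na.rm = TRUE)
  }
  vals <- vapply(seq_len(samples), function(s) one_sample(), numeric(1))
  structure(mean(vals), sd = stats::sd(vals))
}

#' Synthetic whole-genome partition scheme
#'
#' A stand-in for the published whole-genome scheme used to calibrate the
#' random-boundary baseline: hg19 chromosome lengths (chr1-22, X) binned
#' at the given resolution, with `n_partitions` partitions allocated to
#' chromosomes proportionally to their length (largest-remainder rounding,
#' at least one partition each). The per-chromosome counts of the original
#' scheme are not reproduced exactly; this synthetic scheme matches its
#' overall granularity (539 partitions, mean size about 5.7 Mbp).
#'
#' @param n_partitions total number of partitions (default 539).
#' @param resolution bin width in bp (default 50000).
#' @return data frame with columns `chrom`, `n_loci`, `k`.
#' @export
synthetic_genome_scheme <- function(n_partitions = 539, resolution = 50000) {
  lens <- c(chr1 = 249250621, chr2 = 243199373, chr3 = 198022430,
            chr4 = 191154276, chr5 = 180915260, chr6 = 171115067,
            chr7 = 159138663, chr8 = 146364022, chr9 = 141213431,
            chr10 = 135534747, chr11 = 135006516, chr12 = 133851895,
            chr13 = 115169878, chr14 = 107349540, chr15 = 102531392,
            chr16 = 90354753, chr17 = 81195210, chr18 = 78077248,
            chr19 = 59128983, chr20 = 63025520, chr21 = 48129895,
            chr22 = 51304566, chrX = 155270560)
  n_loci <- ceiling(lens / resolution)
  quota <- n_partitions * lens / sum(lens)
  k <- pmax(1L, floor(quota))
  rem <- n_partitions - sum(k)
  if (rem > 0) {
    extra <- order(quota - floor(quota), decreasing = TRUE)[seq_len(rem)]
    k[extra] <- k[extra] + 1L
  }
  data.frame(chrom = names(lens), n_loci = as.integer(n_loci),
             k = as.integer(k), row.names = NULL)
}
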