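#' Binned Hi-C contact matrix
#'
#' Container for a symmetric, non-negative matrix of contact counts between
#' fixed-width genomic bins of one chromosome (or a concatenated genome).
#' Counts may be raw integers or real-valued after Gaussian smoothing.
#'
#' @param counts symmetric non-negative numeric matrix.
#' @param chrom chromosome name.
#' @param resolution bin width in bp.
#' @param bin_starts 0-based bin start coordinates, strictly increasing
#'   multiples of `resolution`. Defaults to contiguous bins from 0.
#' @param smoothed logical flag, set by [gaussian_smooth()].
#' @return an object of class `contact_matrix`.
#' @export
contact_matrix <- function(counts, chrom = "chr1", resolution = 50000L,
                           bin_starts = NULL, smoothed = FALSE) {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  if (ncol(counts) != n) stop("counts must be square")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (max(abs(counts - t(counts))) > 1e-8 * max(1, max(counts)))
    stop("counts must be symmetric")
  counts <- (counts + t(counts)) / 2   # enforce exact symmetry
  if (is.null(bin_starts)) bin_starts <- as.numeric(seq_len(n) - 1L) * resolution
  if (length(bin_starts) != n) stop("bin_starts length must match matrix size")
  if (any(diff(bin_starts) <= 0)) stop("bin_starts must be strictly increasing")
  if (any(bin_starts %% resolution != 0))
    stop("bin_starts must be multiples of the resolution")
  structure(list(counts = counts, chrom = chrom,
                 resolution = as.numeric(resolution),
                 bin_starts = as.numeric(bin_starts),
                 smoothed = isTRUE(smoothed)),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %s: %d bins @ %g bp%s, total counts %.6g\n",
              x$chrom, nrow(x$counts), x$resolution,
              if (x$smoothed) " (smoothed)" else "",
              sum(x$counts)))
  invisible(x)
}

#' @export
dim.contact_matrix <- function(x) dim(x$counts)

#' @export
as.matrix.contact_matrix <- function(x, ...) x$counts

#' Read a sparse-triplet Hi-C contact file
#'
#' Parses the triplet text dialect used for published raw observed
#' intra-chromosomal maps: one line per pair,
#' `start_i<TAB>start_j<TAB>count`, coordinates 0-based multiples of the
#' bin resolution. Duplicate pairs are summed; diagonal (self-pair) entries
#' are stored but excluded from the Markov model downstream.
#'
#' @param path path to the triplet file.
#' @param resolution bin width in bp.
#' @param chrom chromosome name to attach.
#' @param n_bins optional number of bins; default spans the largest
#'   coordinate seen.
#' @return a [contact_matrix()].
#' @export
read_contacts <- function(path, resolution, chrom = "chr1", n_bins = NULL) {
  if (!file.exists(path)) stop("contact file not found: ", path)
  df <- tryCatch(utils::read.table(path, header = FALSE,
                          colClasses = c("numeric", "numeric", "numeric")),
                 error = function(e) NULL)
  if (is.null(df) || nrow(df) == 0) stop("empty contact file: ", path)
  names(df) <- c("start_i", "start_j", "count")
  if (any(df$start_i %% resolution != 0) || any(df$start_j %% resolution != 0))
    stop("coordinate not a multiple of the resolution")
  if (any(df$count < 0)) stop("negative count in contact file")
  i <- df$start_i / resolution + 1L
  j <- df$start_j / resolution + 1L
  n <- if (is.null(n_bins)) max(i, j) else n_bins
  m <- matrix(0, n, n)
  for (k in seq_len(nrow(df))) {
    m[i[k], j[k]] <- m[i[k], j[k]] + df$count[k]
    if (i[k] != j[k]) m[j[k], i[k]] <- m[j[k], i[k]] + df$count[k]
  }
  contact_matrix(m, chrom = chrom, resolution = resolution)
}

#' Write a contact matrix as sparse triplets
#'
#' Inverse of [read_contacts()]: emits the upper triangle (including the
#' diagonal where non-zero) as `start_i start_j count` lines.
#'
#' @param cm a [contact_matrix()].
#' @param path output path.
#' @export
write_contacts <- function(cm, path) {
  m <- cm$counts
  idx <- which(upper.tri(m, diag = TRUE) & m != 0, arr.ind = TRUE)
  df <- data.frame(start_i = cm$bin_starts[idx[, 1]],
                   start_j = cm$bin_starts[idx[, 2]],
                   count = m[idx])
  df <- df[order(df$start_i, df$start_j), ]
  df$start_i <- format(df$start_i, scientific = FALSE, trim = TRUE)
  df$start_j <- format(df$start_j, scientific = FALSE, trim = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Gaussian smoothing of a contact map
#'
#' 2D isotropic convolution of the counts with a truncated Gaussian kernel,
#' the standard preprocessing that suppresses shot noise in raw counts
#' before the contact-energy landscape is built. The kernel has width
#' `sigma_bp` (default 200 kbp) and is truncated at `truncate_sigmas`
#' standard deviations (default 4). Boundaries use zero padding with plain
#' truncation (no kernel renormalization at the edges).
#'
#' @param cm a [contact_matrix()].
#' @param sigma_bp kernel standard deviation in bp; 0 returns the input.
#' @param truncate_sigmas truncation radius in units of sigma.
#' @return the smoothed [contact_matrix()].
#' @export
gaussian_smooth <- function(cm, sigma_bp = 200000, truncate_sigmas = 4) {
  if (sigma_bp < 0) stop("sigma_bp must be >= 0")
  if (sigma_bp == 0) return(cm)
  sigma <- sigma_bp / cm$resolution       # in bins
  r <- ceiling(truncate_sigmas * sigma)
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)                         # normalized 1D kernel; 2D = outer
  n <- nrow(cm$counts)
  # separable convolution via a banded convolution matrix
  K <- matrix(0, n, n)
  for (d in seq(-r, r)) {
    idx <- seq_len(n - abs(d))
    if (d >= 0) K[cbind(idx, idx + d)] <- k[d + r + 1]
    else        K[cbind(idx - d, idx)] <- k[d + r + 1]
  }
  sm <- K %*% cm$counts %*% t(K)
  sm[sm < 0] <- 0                         # clip tiny negative round-off
  out <- contact_matrix((sm + t(sm)) / 2, chrom = cm$chrom,
                        resolution = cm$resolution,
                        bin_starts = cm$bin_starts, smoothed = TRUE)
  out
}

#' Drop loci with no contacts
#'
#' Bins with zero row sum (centromeres, unmappable regions) make the
#' energies and first-passage systems singular; they are removed before the
#' Markov model is built. The returned mask maps reduced-state indices back
#' to genomic bin indices.
#'
#' @param cm a [contact_matrix()].
#' @return list with elements `cm` (reduced [contact_matrix()]) and `mask`
#'   (list: `active` logical over original bins, `index_map` integer vector
#'   of original bin indices for each reduced state).
#' @export
mask_inactive_loci <- function(cm) {
  rs <- rowSums(cm$counts)
  active <- rs > 0
  if (!any(active)) stop("all loci inactive: empty contact matrix")
  index_map <- which(active)
  red <- contact_matrix(cm$counts[active, active, drop = FALSE],
                        chrom = cm$chrom, resolution = cm$resolution,
                        bin_starts = cm$bin_starts[active],
                        smoothed = cm$smoothed)
  list(cm = red, mask = list(active = active, index_map = index_map))
}

#' Write the inactive-loci mask as BED intervals of excluded bins
#' @param mask mask component returned by [mask_inactive_loci()].
#' @param cm the original (unreduced) [contact_matrix()].
#' @param path output path.
#' @export
write_mask_bed <- function(mask, cm, path) {
  excl <- which(!mask$active)
  df <- data.frame(chrom = cm$chrom,
                   start = format(cm$bin_starts[excl], scientific = FALSE,
                                  trim = TRUE),
                   end = format(cm$bin_starts[excl] + cm$resolution,
                                scientific = FALSE, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read/write a dense TSV contact matrix
#' @param path file path.
#' @param resolution bin width in bp.
#' @param chrom chromosome name.
#' @export
read_dense_contacts <- function(path, resolution, chrom = "chr1") {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(m) <- NULL
  contact_matrix(m, chrom = chrom, resolution = resolution)
}

#' @rdname read_dense_contacts
#' @param cm a [contact_matrix()].
#' @export
write_dense_contacts <- function(cm, path) {
  utils::write.table(cm$counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
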