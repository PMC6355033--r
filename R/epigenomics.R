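#' Read a bedGraph signal track
#'
#' @param path 4-column bedGraph file.
#' @return a `GRanges` with a `score` column.
#' @export
read_bedgraph <- function(path) {
  rtracklayer::import(path, format = "bedGraph")
}

#' Read a UCSC cytoBand.txt annotation
#'
#' @param path plain 5-column file (chrom, start, end, name, gieStain).
#' @return data frame with those columns.
#' @export
read_cytoband <- function(path) {
  utils::read.table(path, sep = "\t", header = FALSE,
                    col.names = c("chrom", "start", "end", "name", "gieStain"),
                    stringsAsFactors = FALSE)
}

# partition intervals -> GRanges keyed by partition id
partition_granges <- function(parts, cm) {
  iv <- partition_intervals(parts, cm)
  GenomicRanges::GRanges(iv$chrom,
                         IRanges::IRanges(start = iv$start + 1, end = iv$end),
                         partition = iv$partition)
}

#' Mean signal density per partition
#'
#' Length-weighted mean of a signal track over each partition's genomic
#' intervals; bases not covered by the track contribute 0 signal.
#'
#' @param track a `GRanges` with a `score` column (see [read_bedgraph()]),
#'   with non-overlapping intervals per chromosome.
#' @param parts a [hard_partition()].
#' @param cm matching [contact_matrix()] carrying the coordinates.
#' @return numeric vector of densities, one per partition (1..k).
#' @export
partition_signal_density <- function(track, parts, cm) {
  pg <- partition_granges(parts, cm)
  k <- parts$k
  dens <- numeric(k)
  if (length(track) > 0) {
    if (!any(as.character(GenomicRanges::seqnames(track)) %in%
             as.character(GenomicRanges::seqnames(pg))))
      stop("chromosome name mismatch between track and partitions")
    ov <- GenomicRanges::findOverlaps(pg, track)
    if (length(ov) > 0) {
      inter <- GenomicRanges::pintersect(pg[S4Vectors::queryHits(ov)],
                                         track[S4Vectors::subjectHits(ov)])
      w <- GenomicRanges::width(inter)
      s <- track$score[S4Vectors::subjectHits(ov)]
      p <- pg$partition[S4Vectors::queryHits(ov)]
      mass <- tapply(w * s, factor(p, levels = seq_len(k)), sum)
      mass[is.na(mass)] <- 0
      dens <- as.numeric(mass)
    }
  }
  len <- tapply(GenomicRanges::width(pg),
                factor(pg$partition, levels = seq_len(k)), sum)
  dens / as.numeric(len)
}

#' Factor density table over partitions
#'
#' @param tracks named list of `GRanges` signal tracks, one per factor.
#' @param parts a [hard_partition()].
#' @param cm matching [contact_matrix()].
#' @return object of class `factor_density`: list with `density` (matrix
#'   partitions x factors) and `weights` (partition lengths in bp).
#' @export
factor_density_table <- function(tracks, parts, cm) {
  dens <- vapply(tracks, partition_signal_density, numeric(parts$k),
                 parts = parts, cm = cm)
  dens <- matrix(dens, nrow = parts$k,
                 dimnames = list(NULL, names(tracks)))
  pg <- partition_granges(parts, cm)
  w <- as.numeric(tapply(GenomicRanges::width(pg),
                         factor(pg$partition, levels = seq_len(parts$k)), sum))
  structure(list(density = dens, weights = w), class = "factor_density")
}

#' Z-scored factor densities
#'
#' `Z_f(A) = (x_f(A) - mu_f) / sigma_f` with `mu_f`, `sigma_f` the
#' partition-length-weighted mean and standard deviation of the densities
#' across partitions (whole-genome use pools all partitions). A factor
#' with zero weighted variance gets an all-`NA` column and a warning.
#'
#' @param table a [factor_density_table()], or a plain density matrix.
#' @param weights partition weights (bp lengths); required when `table`
#'   is a plain matrix.
#' @return matrix of Z-scores with the same shape as the densities.
#' @export
zscore_densities <- function(table, weights = NULL) {
  if (inherits(table, "factor_density")) {
    x <- table$density; w <- table$weights
  } else { x <- as.matrix(table); w <- weights }
  if (is.null(w)) stop("weights required")
  if (nrow(x) < 2) stop("need at least 2 partitions")
  w <- w / sum(w)
  z <- x
  for (f in seq_len(ncol(x))) {
    m <- sum(w * x[, f])
    s <- sqrt(sum(w * (x[, f] - m)^2))
    if (s == 0) {
      warning("zero weighted variance for factor ", colnames(x)[f] %||% f)
      z[, f] <- NA_real_
    } else z[, f] <- (x[, f] - m) / s
  }
  z
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Euchromatin/heterochromatin classification of partitions
#'
#' Overlaps each partition with Giemsa-stain bands: a partition is `EC`
#' when more than `threshold` of its length lies in light bands
#' (gneg, gpos25), `HC` when more than `threshold` lies in dark bands
#' (gpos50, gpos75, gpos100), and `mixed` otherwise. Centromeric and
#' variable bands (acen, gvar, stalk) count toward neither class.
#'
#' @param bands cytoband data frame (see [read_cytoband()]).
#' @param parts a [hard_partition()].
#' @param cm matching [contact_matrix()].
#' @param threshold dominance fraction (default 0.8).
#' @return object of class `chromatin_class`: data frame with per-class
#'   length fractions and a `class` column.
#' @export
classify_ec_hc <- function(bands, parts, cm, threshold = 0.8) {
  pg <- partition_granges(parts, cm)
  bg <- GenomicRanges::GRanges(bands$chrom,
                               IRanges::IRanges(bands$start + 1, bands$end),
                               stain = bands$gieStain)
  k <- parts$k
  stains <- c("gneg", "gpos25", "gpos50", "gpos75", "gpos100",
              "acen", "gvar", "stalk")
  frac <- matrix(0, k, length(stains), dimnames = list(NULL, stains))
  ov <- GenomicRanges::findOverlaps(pg, bg)
  if (length(ov) > 0) {
    inter <- GenomicRanges::pintersect(pg[S4Vectors::queryHits(ov)],
                                       bg[S4Vectors::subjectHits(ov)])
    w <- GenomicRanges::width(inter)
    p <- pg$partition[S4Vectors::queryHits(ov)]
    s <- bg$stain[S4Vectors::subjectHits(ov)]
    for (st in stains) {
      sel <- s == st
      if (any(sel)) {
        m <- tapply(w[sel], factor(p[sel], levels = seq_len(k)), sum)
        m[is.na(m)] <- 0
        frac[, st] <- as.numeric(m)
      }
    }
  }
  len <- as.numeric(tapply(GenomicRanges::width(pg),
                           factor(pg$partition, levels = seq_len(k)), sum))
  frac <- frac / len
  covered <- rowSums(frac)
  ec <- frac[, "gneg"] + frac[, "gpos25"]
  hc <- frac[, "gpos50"] + frac[, "gpos75"] + frac[, "gpos100"]
  cls <- ifelse(ec > threshold, "EC", ifelse(hc > threshold, "HC", "mixed"))
  if (any(covered == 0)) {
    warning("partition(s) with zero band overlap classified as mixed")
    cls[covered == 0] <- "mixed"
  }
  out <- data.frame(partition = seq_len(k), frac, ec_frac = ec, hc_frac = hc,
                    class = cls)
  class(out) <- c("chromatin_class", class(out))
  out
}

#' Enrichment-product vs interaction regression
#'
#' Across qualifying partition pairs of a given chromatin-class
#' combination, regresses the log product of factor densities on the log
#' effective interaction: `ln(x_f(A) x_f(B)) ~ ln F_AB`. Pairs with
#' non-positive interaction or density product are dropped (log
#' undefined) and counted.
#'
#' @param eff an `effective_interactions` object (or matrix).
#' @param density numeric vector of one factor's densities per partition.
#' @param classes `chromatin_class` table (or character vector of
#'   classes); `NULL` disables class filtering.
#' @param pair_class one of `"EC-EC"`, `"HC-HC"`, `"EC-HC"`, `"all"`.
#' @return list with `slope`, `r` (Pearson, log-log), `p` (two-sided),
#'   `n_pairs`, `n_dropped`.
#' @export
enrichment_correlation <- function(eff, density, classes = NULL,
                                   pair_class = c("all", "EC-EC", "HC-HC",
                                                  "EC-HC")) {
  pair_class <- match.arg(pair_class)
  Fm <- if (inherits(eff, "effective_interactions")) eff$F else eff
  k <- nrow(Fm)
  cls <- if (is.null(classes)) rep("any", k)
         else if (is.data.frame(classes)) classes$class else classes
  idx <- which(upper.tri(Fm), arr.ind = TRUE)
  if (pair_class != "all") {
    want <- sort(strsplit(pair_class, "-")[[1]])
    pc <- cbind(cls[idx[, 1]], cls[idx[, 2]])
    keep <- pc[, 1] != "mixed" & pc[, 2] != "mixed" &
      apply(pc, 1, function(r) identical(sort(r), want))
    idx <- idx[keep, , drop = FALSE]
  }
  f <- Fm[idx]
  prod <- density[idx[, 1]] * density[idx[, 2]]
  ok <- f > 0 & prod > 0
  n_dropped <- sum(!ok)
  f <- f[ok]; prod <- prod[ok]
  if (length(f) < 3) stop("insufficient data: fewer than 3 qualifying pairs")
  x <- log(f); y <- log(prod)
  if (stats::sd(y) == 0)
    return(list(slope = 0, r = 0, p = 1, n_pairs = length(f),
                n_dropped = n_dropped))
  fit <- stats::lm(y ~ x)
  ct <- stats::cor.test(x, y)
  list(slope = unname(stats::coef(fit)[2]), r = unname(ct$estimate),
       p = ct$p.value, n_pairs = length(f), n_dropped = n_dropped)
}
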