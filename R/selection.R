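#' Per-SNP Weir-Cockerham F_ST between two populations
#'
#' The Weir-Cockerham (1984) theta-hat per marker from genotype counts
#' (variance components a, b, c with observed heterozygosity), for the two
#' groups defined by `origin`. Negative estimates are truncated to 0 in
#' `fst` while the signed value is kept in `fst_signed`. Markers genotyped
#' in fewer than 2 samples of either population get `NA` (flagged missing).
#'
#' @param x a [GenotypeData-class] object whose [sampleInfo()] has a
#'   two-level `origin` column.
#' @param origin optional explicit vector of population labels per sample.
#' @return data.frame with `marker_id`, `fst_signed`, `fst`.
#' @export
fstPerSnp <- function(x, origin = NULL) {
  d <- dosages(x)
  if (is.null(origin)) origin <- sampleInfo(x)$origin
  origin <- as.character(origin)
  labs <- sort(unique(origin[!is.na(origin)]))
  stopifnot(length(labs) == 2)
  g1 <- which(origin == labs[1]); g2 <- which(origin == labs[2])
  cnt <- function(idx) {
    dd <- d[, idx, drop = FALSE]
    cbind(n0 = rowSums(dd == 0L, na.rm = TRUE),
          n1 = rowSums(dd == 1L, na.rm = TRUE),
          n2 = rowSums(dd == 2L, na.rm = TRUE))
  }
  th <- fstFromCounts(cnt(g1), cnt(g2))
  data.frame(marker_id = rownames(d), fst_signed = th, fst = pmax(th, 0))
}

#' Weir-Cockerham theta-hat from genotype count tables
#'
#' Vectorized two-population estimator: rows of `counts1`/`counts2` are
#' markers, columns the genotype counts (`n0`, `n1`, `n2` copies of the B
#' allele). With `components = TRUE` the per-marker variance components
#' (a, b, c) are returned instead, from which the standard multi-locus
#' ratio-of-sums estimator `sum(a) / sum(a + b + c)` can be formed (see
#' [fstGlobal()]).
#'
#' @param counts1,counts2 integer matrices with columns n0, n1, n2.
#' @param components return the per-marker (a, b, c) matrix instead of the
#'   per-marker ratio.
#' @return numeric vector of signed theta-hat (NA where either population
#'   has < 2 genotyped samples or the marker is monomorphic overall), or a
#'   3-column matrix of variance components.
#' @export
fstFromCounts <- function(counts1, counts2, components = FALSE) {
  n1 <- rowSums(counts1); n2 <- rowSums(counts2)
  p1 <- (counts1[, 2] + 2 * counts1[, 3]) / (2 * n1)
  p2 <- (counts2[, 2] + 2 * counts2[, 3]) / (2 * n2)
  h1 <- counts1[, 2] / n1
  h2 <- counts2[, 2] / n2
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  bad <- n1 < 2 | n2 < 2
  if (components) {
    out <- cbind(a = a, b = b, c = cc)
    out[bad, ] <- NA_real_
    return(out)
  }
  theta <- a / (a + b + cc)
  theta[bad] <- NA_real_
  theta[(a + b + cc) == 0] <- NA_real_
  theta
}

#' Multi-locus Weir-Cockerham theta (ratio of sums)
#'
#' The standard genome-wide estimator: variance components are summed over
#' markers before the ratio is formed, `theta = sum(a) / sum(a + b + c)`.
#' Under the Balding-Nichols model with drift parameter `c` this recovers
#' `c` (the per-marker ratio average is biased downward by the ratio
#' nonlinearity).
#'
#' @inheritParams fstFromCounts
#' @return a single theta estimate.
#' @export
fstGlobal <- function(counts1, counts2) {
  comp <- fstFromCounts(counts1, counts2, components = TRUE)
  comp <- comp[stats::complete.cases(comp), , drop = FALSE]
  sum(comp[, "a"]) / sum(comp)
}

#' Empirical percentile threshold
#'
#' Order-statistic percentile with linear interpolation between closest
#' ranks (the `h = (n-1) p + 1` convention). Values strictly greater than
#' the returned bound are called outliers.
#'
#' @param values finite numeric values (length >= 1).
#' @param percentile percentile in `[0, 100]` (default 99.999).
#' @return the threshold.
#' @export
empiricalPercentileThreshold <- function(values, percentile = 99.999) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("no finite values")
  unname(quantile(values, percentile / 100, type = 7))
}

#' Window-smoothed F_ST
#'
#' Non-overlapping windows of `window_bp` tiled from position 1 on each
#' chromosome (half-open `[k w + 1, (k+1) w + 1)` in 1-based terms); the
#' window statistic is the mean truncated F_ST of contained SNPs. Windows
#' with fewer than `min_snps` SNPs are discarded; empty windows are never
#' emitted.
#'
#' @param fst per-marker truncated F_ST (aligned with `map`).
#' @param map a marker map data.frame ([markerMap()]).
#' @param window_bp window width in bp (default 500 kb).
#' @param min_snps minimum SNPs per retained window (default 4).
#' @return data.frame with `chromosome`, `start_bp`, `end_bp` (half-open),
#'   `n_snps`, `mean_fst`.
#' @export
smoothFstWindows <- function(fst, map, window_bp = 500000, min_snps = 4) {
  stopifnot(length(fst) == nrow(map))
  win <- (map$position_bp - 1) %/% window_bp
  key <- paste(map$chromosome, win, sep = ":")
  ok <- !is.na(fst)
  agg <- tapply(fst[ok], key[ok], mean)
  nsnp <- tapply(fst[ok], key[ok], length)
  parts <- do.call(rbind, strsplit(names(agg), ":"))
  out <- data.frame(chromosome = parts[, 1],
                    start_bp = as.numeric(parts[, 2]) * window_bp + 1,
                    end_bp = (as.numeric(parts[, 2]) + 1) * window_bp + 1,
                    n_snps = as.integer(nsnp), mean_fst = as.numeric(agg))
  out <- out[out$n_snps >= min_snps, , drop = FALSE]
  out <- out[order(.chromOrder(out$chromosome), out$start_bp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' FLK neutrality test
#'
#' Tests each marker's population allele frequencies against the neutral
#' drift expectation encoded by the kinship matrix `F` of a population tree.
#' Per marker the ancestral frequency is estimated by generalized least
#' squares, `p0 = (1' F^-1 p) / (1' F^-1 1)`, and the statistic
#' `T = (p - p0 1)' F^-1 (p - p0 1) / (p0 (1 - p0))` is referred to a
#' chi-squared distribution with `npop - 1` degrees of freedom. Markers with
#' an estimated ancestral frequency outside (0, 1) are flagged `NA`.
#'
#' @param pop_freqs numeric matrix, populations x markers, of B-allele
#'   frequencies; rownames must match the tree labels when `tree` is a
#'   [PopTree-class].
#' @param tree a [PopTree-class] object, or a positive-definite drift matrix
#'   `F` directly.
#' @return data.frame with `flk_stat` and `flk_p` per marker.
#' @export
flkTest <- function(pop_freqs, tree) {
  F <- if (is(tree, "PopTree")) driftMatrix(tree) else tree
  stopifnot(is.matrix(F), nrow(F) == nrow(pop_freqs))
  if (!is.null(rownames(F)) && !is.null(rownames(pop_freqs)))
    F <- F[rownames(pop_freqs), rownames(pop_freqs)]
  npop <- nrow(F)
  Finv <- tryCatch(solve(F), error = function(e)
    stop("drift matrix of the population tree is singular"))
  one <- rep(1, npop)
  w <- as.vector(Finv %*% one)
  denom <- sum(w)
  p0 <- as.vector(crossprod(w, pop_freqs)) / denom
  dev <- sweep(pop_freqs, 2, p0)
  Tq <- colSums(dev * (Finv %*% dev))
  stat <- Tq / (p0 * (1 - p0))
  bad <- !(p0 > 0 & p0 < 1)
  stat[bad] <- NA_real_
  data.frame(flk_stat = stat,
             flk_p = pchisq(stat, df = npop - 1, lower.tail = FALSE))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values with monotonicity enforcement, capped at 1
#' (delegates to [stats::p.adjust()]). NA values are passed through.
#'
#' @param p p-values in `[0, 1]`.
#' @return adjusted p-values.
#' @export
fdrBH <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Call selection outliers
#'
#' Combines the empirical-percentile rules on per-SNP and window-mean F_ST
#' with FLK FDR significance. Per-SNP outliers exceed (strictly) the
#' `fst_percentile` bound of the per-SNP F_ST distribution; window outliers
#' exceed the same percentile of the window means; FLK-significant markers
#' have an FDR-adjusted p-value below or equal to `flk_fdr_max`.
#'
#' @param scan data.frame with at least `marker_id` and `fst`; optionally
#'   `flk_p` (adjusted internally) or `flk_p_fdr`.
#' @param windows window table from [smoothFstWindows()] (optional).
#' @param fst_percentile percentile for the empirical bounds (default
#'   99.999).
#' @param flk_fdr_max FLK FDR threshold (default 0.1, "below or equal").
#' @return list with `fst_threshold`, `fst_outliers`, `window_threshold`,
#'   `window_outliers`, `flk_significant`, `intersection` (marker ids passing
#'   both the per-SNP F_ST and FLK rules).
#' @export
callOutliers <- function(scan, windows = NULL, fst_percentile = 99.999,
                         flk_fdr_max = 0.1) {
  thr <- empiricalPercentileThreshold(scan$fst, fst_percentile)
  fst_out <- scan$marker_id[!is.na(scan$fst) & scan$fst > thr]
  wthr <- NA_real_; wout <- NULL
  if (!is.null(windows) && nrow(windows)) {
    wthr <- empiricalPercentileThreshold(windows$mean_fst, fst_percentile)
    wout <- windows[windows$mean_fst > wthr, , drop = FALSE]
  }
  flk_sig <- character(0)
  if (!is.null(scan$flk_p_fdr) || !is.null(scan$flk_p)) {
    fdr <- if (!is.null(scan$flk_p_fdr)) scan$flk_p_fdr else fdrBH(scan$flk_p)
    flk_sig <- scan$marker_id[!is.na(fdr) & fdr <= flk_fdr_max]
  }
  list(fst_threshold = thr, fst_outliers = fst_out,
       window_threshold = wthr, window_outliers = wout,
       flk_significant = flk_sig,
       intersection = intersect(fst_out, flk_sig))
}

#' Per-population allele frequencies
#'
#' @param x a [GenotypeData-class] object.
#' @param group grouping column of [sampleInfo()] (default `"origin"`).
#' @return matrix, groups x markers, of B-allele sample frequencies.
#' @export
populationFrequencies <- function(x, group = "origin") {
  si <- sampleInfo(x)
  g <- as.character(si[[group]])
  labs <- sort(unique(g[!is.na(g)]))
  d <- dosages(x)
  out <- t(sapply(labs, function(l)
    rowMeans(d[, g == l & !is.na(g), drop = FALSE], na.rm = TRUE) / 2))
  rownames(out) <- labs
  out
}
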