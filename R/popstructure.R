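#' Genomic relationship matrix
#'
#' VanRaden method-1 (the default): missing dosages are mean-imputed per
#' marker, dosages are centred at `2p` and `GRM = Z'Z / sum(2 p (1-p))`,
#' with `p` the sample frequency of the B allele. The `"ibs"` alternative
#' returns the mean identity-by-state similarity rescaled to `[-1, 1]`.
#'
#' @param x a [GenotypeData-class] object (>= 2 samples, >= 1 polymorphic
#'   marker).
#' @param method `"vanraden"` (default) or `"ibs"`.
#' @return symmetric n x n numeric matrix with sample ids as dimnames.
#' @export
computeGRM <- function(x, method = c("vanraden", "ibs")) {
  method <- match.arg(method)
  d <- dosages(x)
  stopifnot(ncol(d) >= 2)
  p <- rowMeans(d, na.rm = TRUE) / 2
  poly <- is.finite(p) & p > 0 & p < 1
  if (!any(poly)) stop("all markers are monomorphic; GRM undefined")
  d <- d[poly, , drop = FALSE]
  p <- p[poly]
  Z <- d - 2 * p                # recycles by column: markers x samples
  Z[is.na(Z)] <- 0              # mean imputation after centring
  if (method == "vanraden") {
    K <- crossprod(Z) / sum(2 * p * (1 - p))
  } else {
    # IBS similarity 1 - |di - dj|/2 averaged over pairwise-complete markers
    S <- matrix(0, ncol(d), ncol(d))
    for (i in seq_len(ncol(d))) {
      dif <- abs(d - d[, i])
      S[, i] <- colMeans(1 - dif / 2, na.rm = TRUE)
    }
    K <- 2 * (S + t(S)) / 2 - 1
  }
  dimnames(K) <- list(colnames(dosages(x)), colnames(dosages(x)))
  K
}

#' Principal components of a relationship matrix
#'
#' Top-`k` eigenvectors of the (symmetric) GRM scaled by the square root of
#' their eigenvalues; the percent variance of component `i` is
#' `100 * lambda_i / trace(K)`. Sign convention: the largest-magnitude
#' loading of each component is positive.
#'
#' @param K symmetric relationship matrix (e.g. from [computeGRM()]).
#' @param k number of components (default 10, capped at n).
#' @return list with `scores` (n x k), `pct_variance` (length k) and
#'   `values` (all eigenvalues).
#' @export
pcaGRM <- function(K, k = 10) {
  if (any(!is.finite(K))) stop("GRM contains non-finite values")
  n <- nrow(K)
  k <- min(k, n)
  e <- eigen((K + t(K)) / 2, symmetric = TRUE)
  tr <- sum(diag(K))
  pct <- 100 * e$values / tr
  scores <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(scores[, j]))
    if (scores[i, j] < 0) scores[, j] <- -scores[, j]
    scores[, j] <- scores[, j] * sqrt(max(e$values[j], 0))
  }
  rownames(scores) <- rownames(K)
  colnames(scores) <- sprintf("PC%d", seq_len(k))
  list(scores = scores, pct_variance = pct[seq_len(k)], values = e$values)
}

#' Reynolds genetic distance between two populations
#'
#' Coancestry distance `D = -ln(1 - theta)` with `theta` a ratio-of-sums
#' moment estimator over markers. Per marker, the squared frequency contrast
#' is debiased by the binomial sampling terms, and the denominator adds the
#' finite-sample-corrected within-population gene diversities:
#' `N_l = (p1-p2)^2 - p1 q1/(2 n1 - 1) - p2 q2/(2 n2 - 1)`,
#' `theta = sum(N_l) / sum(N_l + h1_l + h2_l)` with
#' `h_i = 2 n_i p_i q_i * 2/(2 n_i - 1)`. Under the Balding-Nichols model
#' with drift `c` in each population, `theta` estimates `c`.
#'
#' @param freqs_pop1,freqs_pop2 per-marker B-allele frequencies.
#' @param n1,n2 sample counts (individuals) behind each frequency vector
#'   (scalars or per-marker vectors).
#' @return the distance `D` (may be slightly negative for identical
#'   populations at finite sampling; `Inf` when `theta >= 1`).
#' @export
reynoldsDistance <- function(freqs_pop1, freqs_pop2, n1, n2) {
  stopifnot(length(freqs_pop1) == length(freqs_pop2), all(n1 >= 2), all(n2 >= 2))
  p1 <- freqs_pop1; p2 <- freqs_pop2
  ok <- is.finite(p1) & is.finite(p2)
  p1 <- p1[ok]; p2 <- p2[ok]
  if (length(n1) > 1) n1 <- n1[ok]
  if (length(n2) > 1) n2 <- n2[ok]
  h1 <- 2 * p1 * (1 - p1) * 2 * n1 / (2 * n1 - 1)
  h2 <- 2 * p2 * (1 - p2) * 2 * n2 / (2 * n2 - 1)
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (2 * n1 - 1) - p2 * (1 - p2) / (2 * n2 - 1)
  theta <- 2 * sum(num) / sum(2 * num + h1 + h2)
  if (theta >= 1) return(Inf)
  -log(1 - theta)
}

#' Pairwise Reynolds distance matrix over sample groups
#'
#' @param x a [GenotypeData-class] object.
#' @param group name of the grouping column in [sampleInfo()] (default
#'   `"origin"`).
#' @return symmetric matrix of Reynolds distances between groups.
#' @export
reynoldsDistanceMatrix <- function(x, group = "origin") {
  si <- sampleInfo(x)
  g <- as.character(si[[group]])
  stopifnot(!is.null(g), !all(is.na(g)))
  labs <- sort(unique(g[!is.na(g)]))
  d <- dosages(x)
  freqs <- sapply(labs, function(l)
    rowMeans(d[, g == l & !is.na(g), drop = FALSE], na.rm = TRUE) / 2)
  ns <- sapply(labs, function(l) sum(g == l, na.rm = TRUE))
  D <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  for (i in seq_along(labs)) for (j in seq_along(labs)) if (i < j) {
    D[i, j] <- D[j, i] <- max(0, reynoldsDistance(freqs[, i], freqs[, j],
                                                  ns[i], ns[j]))
  }
  D
}

#' Neighbor-joining population tree with drift matrix
#'
#' Saitou-Nei neighbor joining on a distance matrix over populations;
#' negative branch lengths are clipped to 0. For two populations the single
#' edge is split between the leaves in ratio `root_split` (default equal:
#' rooting is unidentifiable without an outgroup). Trees with three or more
#' leaves are midpoint-rooted. The drift matrix `F` is the shared-branch-
#' length (variance-covariance) matrix of the rooted tree, as consumed by
#' [flkTest()].
#'
#' @param D symmetric non-negative distance matrix with dimnames.
#' @param root_split for 2 populations, fraction of the edge assigned to the
#'   first leaf (default 0.5).
#' @return a [PopTree-class] object.
#' @export
popTreeNJ <- function(D, root_split = 0.5) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D), nrow(D) >= 2,
            max(abs(D - t(D))) < 1e-8, root_split > 0, root_split < 1)
  labs <- rownames(D)
  if (is.null(labs)) labs <- sprintf("pop%d", seq_len(nrow(D)))
  if (nrow(D) == 2) {
    bl <- c(root_split, 1 - root_split) * D[1, 2]
    tr <- ape::read.tree(text = sprintf("(%s:%.10g,%s:%.10g);",
                                        labs[1], bl[1], labs[2], bl[2]))
    F <- diag(bl)
    dimnames(F) <- list(labs, labs)
    return(new("PopTree", tree = tr, F = F, labels = labs))
  }
  tr <- ape::nj(as.dist(D))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr <- phangorn::midpoint(tr)
  F <- ape::vcv(tr)
  F <- F[labs, labs]
  new("PopTree", tree = tr, F = F, labels = labs)
}
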