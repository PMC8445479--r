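#' REML variance components of the null mixed model
#'
#' Fits `y = mu + u + e` with `u ~ (0, sigma_g^2 K)` by restricted maximum
#' likelihood, profiling the likelihood in `delta = sigma_e^2 / sigma_g^2`
#' on the spectrum of the projected kinship matrix: a log-spaced grid over
#' `[1e-5, 1e5]` refined by [stats::optimize()] (golden-section) in the best
#' bracket. The binary origin phenotype is treated as quantitative. A ridge
#' of 1e-6 is added when `K` is not positive semi-definite.
#'
#' @param y numeric phenotype vector (finite, non-constant).
#' @param K kinship/GRM matrix aligned with `y`.
#' @return list of class `"MixedModelNull"` with `sigma_g2`, `sigma_e2`,
#'   `delta`, `h2`, `loglik` (profiled REML), and the eigendecomposition
#'   (`U`, `d`) of `K` reused by [emmaxScan()].
#' @export
fitNullMixedModel <- function(y, K) {
  y <- as.numeric(y)
  n <- length(y)
  stopifnot(all(is.finite(y)), nrow(K) == n)
  if (var(y) == 0) stop("phenotype is constant; no variance to model")
  K <- (K + t(K)) / 2
  eK <- eigen(K, symmetric = TRUE)
  if (min(eK$values) < -1e-8) {
    K <- K + diag(1e-6, n)
    eK <- eigen(K, symmetric = TRUE)
  }
  # REML projection: spectrum of S K S restricted to the n-1 dim complement
  # of the intercept
  S <- diag(n) - matrix(1 / n, n, n)
  eS <- eigen(S %*% K %*% S, symmetric = TRUE)
  xi <- pmax(eS$values[seq_len(n - 1)], 0)
  eta <- crossprod(eS$vectors[, seq_len(n - 1), drop = FALSE], y)[, 1]
  negll <- function(logd) {
    delta <- exp(logd)
    r <- sum(eta^2 / (xi + delta))
    (n - 1) * log(r) + sum(log(xi + delta))
  }
  grid <- seq(log(1e-5), log(1e5), length.out = 61)
  vals <- vapply(grid, negll, 0)
  i <- which.min(vals)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- optimize(negll, c(lo, hi), tol = 1e-10)
  delta <- exp(opt$minimum)
  sigma_g2 <- sum(eta^2 / (xi + delta)) / (n - 1)
  sigma_e2 <- delta * sigma_g2
  out <- list(sigma_g2 = sigma_g2, sigma_e2 = sigma_e2, delta = delta,
              h2 = sigma_g2 / (sigma_g2 + sigma_e2),
              loglik = -0.5 * (opt$objective +
                                 (n - 1) * (1 + log(2 * pi / (n - 1)))),
              U = eK$vectors, d = eK$values)
  class(out) <- "MixedModelNull"
  out
}

#' @export
print.MixedModelNull <- function(x, ...) {
  cat(sprintf("Null mixed model: sigma_g2 = %.4g, sigma_e2 = %.4g (h2 = %.3f, delta = %.4g)\n",
              x$sigma_g2, x$sigma_e2, x$h2, x$delta))
  invisible(x)
}

#' EMMAX-style single-locus mixed-model association scan
#'
#' Variance components from the null model are held fixed (the EMMAX
#' approximation). The data are rotated by `V^{-1/2}` using the
#' eigendecomposition of the GRM and each SNP is tested by generalized
#' least squares with an intercept: Wald t-test on `n - 2` degrees of
#' freedom. Missing dosages are mean-imputed per marker; monomorphic SNPs
#' are skipped with an NA flag. FDR adjustment is Benjamini-Hochberg. The
#' proportion of phenotypic variance explained is
#' `pve = beta^2 var(g) / var(y)`, and the genomic inflation factor is
#' `lambda = median(observed chi-squared quantiles) / 0.4549364`.
#'
#' @param x a [GenotypeData-class] object.
#' @param y phenotype vector aligned with the samples (e.g. origin coded
#'   0 = island, 1 = mainland).
#' @param null a `"MixedModelNull"` fit from [fitNullMixedModel()] on the
#'   same samples.
#' @return data.frame with `marker_id`, `beta_hat`, `se`, `p_value`,
#'   `p_fdr`, `pve`, `significant` (FDR < 0.05), plus attributes `lambda`
#'   and `qq` (expected and observed -log10 p for a Q-Q plot).
#' @export
emmaxScan <- function(x, y, null) {
  d <- dosages(x)
  y <- as.numeric(y)
  n <- ncol(d)
  stopifnot(length(y) == n, inherits(null, "MixedModelNull"))
  G <- d
  mu <- rowMeans(G, na.rm = TRUE)
  for (j in which(rowSums(is.na(G)) > 0)) G[j, is.na(G[j, ])] <- mu[j]
  vg <- apply(G, 1, var)
  mono <- vg == 0 | !is.finite(vg)
  w <- 1 / sqrt(pmax(null$d, 0) + null$delta)
  A <- t(null$U) * w            # rows scaled: A = diag(w) U'
  ys <- A %*% y
  ones <- A %*% rep(1, n)
  Gs <- tcrossprod(A, G)        # n x m rotated genotypes
  a11 <- sum(ones^2)
  b1 <- sum(ones * ys)
  yy <- sum(ys^2)
  a12 <- crossprod(ones, Gs)[1, ]
  a22 <- colSums(Gs^2)
  b2 <- crossprod(ys, Gs)[1, ]
  det <- a11 * a22 - a12^2
  det[mono] <- NA_real_   # skip monomorphic SNPs cleanly
  beta <- (a11 * b2 - a12 * b1) / det
  alpha <- (a22 * b1 - a12 * b2) / det
  rss <- yy - alpha * b1 - beta * b2
  sigma2 <- rss / (n - 2)
  se <- sqrt(sigma2 * a11 / det)
  tstat <- beta / se
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  beta[mono] <- se[mono] <- p[mono] <- NA_real_
  pfdr <- fdrBH(p)
  pve <- beta^2 * vg / var(y)
  chi <- qchisq(p, df = 1, lower.tail = FALSE)
  lambda <- median(chi, na.rm = TRUE) / qchisq(0.5, df = 1, lower.tail = FALSE)
  res <- data.frame(marker_id = rownames(d), beta_hat = beta, se = se,
                    p_value = p, p_fdr = pfdr, pve = pve,
                    significant = !is.na(pfdr) & pfdr < 0.05)
  ok <- which(!is.na(p))
  r <- rank(p[ok], ties.method = "first")
  qq <- data.frame(expected = -log10((r - 0.5) / length(ok)),
                   observed = -log10(p[ok]))
  attr(res, "lambda") <- lambda
  attr(res, "qq") <- qq[order(qq$expected), ]
  res
}

#' Genomic inflation factor of a p-value set
#'
#' @param p p-values.
#' @return `median(qchisq(1 - p, 1)) / 0.4549364`.
#' @export
genomicInflation <- function(p) {
  median(qchisq(p, df = 1, lower.tail = FALSE), na.rm = TRUE) /
    qchisq(0.5, df = 1, lower.tail = FALSE)
}
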