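#' Sample call-rate filter
#'
#' Removes samples whose fraction of non-missing genotypes is strictly below
#' `threshold` (default 0.95).
#'
#' @param x a [GenotypeData-class] object.
#' @param threshold minimum call rate in (0, 1].
#' @return list with `geno` (filtered object) and `excluded_ids`.
#' @export
sampleCallRateFilter <- function(x, threshold = 0.95) {
  stopifnot(threshold >= 0, threshold <= 1)
  d <- dosages(x)
  cr <- colMeans(!is.na(d))
  drop <- cr < threshold
  if (all(drop))
    stop("all samples fail the call-rate filter; review the threshold")
  list(geno = x[, !drop], excluded_ids = colnames(d)[drop])
}

#' Per-sample call rates
#' @param x a [GenotypeData-class] object.
#' @return named numeric vector of per-sample fractions of non-missing calls.
#' @export
sampleCallRates <- function(x) colMeans(!is.na(dosages(x)))

#' Method-of-moments IBD estimates (pi-hat)
#'
#' Estimates P(IBD=0), P(IBD=1), P(IBD=2) for every sample pair from
#' identity-by-state counts in the PLINK `--genome` convention, using sample
#' allele frequencies, and returns `pihat = P(IBD=1)/2 + P(IBD=2)` clipped
#' to `[0, 1]`. Missing genotypes are handled pairwise-complete; expected
#' IBS counts are scaled by the pair's complete-marker fraction.
#'
#' @param x a [GenotypeData-class] object with at least 2 samples.
#' @return symmetric n x n matrix of pi-hat with unit diagonal.
#' @export
estimatePihat <- function(x) {
  d <- dosages(x)
  n <- ncol(d)
  stopifnot(n >= 2)
  p <- rowMeans(d, na.rm = TRUE) / 2
  poly <- is.finite(p) & p > 0 & p < 1
  if (!any(poly))
    stop("no polymorphic markers: pi-hat is not estimable")
  d <- d[poly, , drop = FALSE]
  p <- p[poly]
  q <- 1 - p
  I0 <- (!is.na(d) & d == 0L) * 1
  I1 <- (!is.na(d) & d == 1L) * 1
  I2 <- (!is.na(d) & d == 2L) * 1
  M <- (!is.na(d)) * 1
  V <- crossprod(M)                      # complete markers per pair
  ibs0 <- crossprod(I0, I2); ibs0 <- ibs0 + t(ibs0)
  ibs2 <- crossprod(I0) + crossprod(I1) + crossprod(I2)
  ibs1 <- V - ibs0 - ibs2
  m <- length(p)
  # expected IBS counts conditional on IBD state, totalled over markers
  e0_0 <- sum(2 * p^2 * q^2)
  e1_0 <- sum(4 * p^3 * q + 4 * p * q^3)
  e1_1 <- sum(2 * p^2 * q + 2 * p * q^2)
  e2_0 <- sum(p^4 + q^4 + 4 * p^2 * q^2)
  e2_1 <- sum(p^3 + q^3 + p^2 * q + p * q^2)
  f <- V / m                             # pairwise-complete scaling
  z0 <- ibs0 / (e0_0 * f)
  z1 <- (ibs1 - z0 * e1_0 * f) / (e1_1 * f)
  z2 <- (ibs2 - z0 * e2_0 * f - z1 * e2_1 * f) / V
  z0 <- pmin(pmax(z0, 0), 1); z1 <- pmin(pmax(z1, 0), 1); z2 <- pmin(pmax(z2, 0), 1)
  s <- z0 + z1 + z2
  pihat <- (z1 / 2 + z2) / s
  pihat <- pmin(pmax(pihat, 0), 1)
  diag(pihat) <- 1
  dimnames(pihat) <- list(colnames(dosages(x)), colnames(dosages(x)))
  pihat
}

#' Greedy pruning of related samples
#'
#' While any pair exceeds the pi-hat threshold, the sample participating in
#' the most offending pairs is removed; ties are broken by lower call rate,
#' then by lexicographically smaller id. The returned set contains no pair
#' with pi-hat above the threshold.
#'
#' @param pihat symmetric matrix from [estimatePihat()].
#' @param threshold pi-hat cutoff in (0, 1); default 0.25 (second-degree
#'   relatives).
#' @param call_rates optional named per-sample call rates for tie-breaking.
#' @return character vector of retained sample ids.
#' @export
pruneRelated <- function(pihat, threshold = 0.25, call_rates = NULL) {
  stopifnot(threshold > 0, threshold < 1)
  ids <- rownames(pihat)
  if (is.null(call_rates)) call_rates <- setNames(rep(1, length(ids)), ids)
  keep <- ids
  repeat {
    sub <- pihat[keep, keep, drop = FALSE]
    off <- sub > threshold
    diag(off) <- FALSE
    deg <- rowSums(off)
    if (!any(deg > 0)) break
    cand <- keep[deg == max(deg)]
    cr <- call_rates[cand]
    cand <- cand[cr == min(cr)]
    drop <- sort(cand)[1]
    keep <- setdiff(keep, drop)
  }
  keep
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact two-sided HWE p-value obtained by enumerating all heterozygote
#' counts conditional on the observed allele counts and summing the
#' probabilities of configurations no more probable than the observed one.
#' Monomorphic markers return p = 1. Vectorized over genotype-count triples.
#'
#' @param n_AA,n_AB,n_BB non-negative genotype counts (equal-length vectors).
#' @return numeric vector of p-values in `[0, 1]`.
#' @export
hweExactTest <- function(n_AA, n_AB, n_BB) {
  stopifnot(length(n_AA) == length(n_AB), length(n_AB) == length(n_BB),
            all(n_AA >= 0), all(n_AB >= 0), all(n_BB >= 0))
  vapply(seq_along(n_AA), function(i) {
    naa <- n_AA[i]; nab <- n_AB[i]; nbb <- n_BB[i]
    n <- naa + nab + nbb
    if (n < 1) stop("genotype counts sum to zero")
    nA <- 2 * naa + nab
    nB <- 2 * nbb + nab
    if (nA == 0 || nB == 0) return(1)
    kmax <- min(nA, nB)
    ks <- seq(kmax %% 2, kmax, by = 2)   # parity fixed by allele counts
    lp <- lfactorial(n) - lfactorial((nA - ks) / 2) - lfactorial(ks) -
      lfactorial((nB - ks) / 2) + ks * log(2) +
      lfactorial(nA) + lfactorial(nB) - lfactorial(2 * n)
    pr <- exp(lp - max(lp))
    pr <- pr / sum(pr)
    obs <- pr[match(nab, ks)]
    min(1, sum(pr[pr <= obs * (1 + 1e-10)]))
  }, 0)
}

#' Marker-level quality control
#'
#' Applies the fixed-precedence marker filters: non-autosomal, then call
#' rate (< `callrate_min`), then minor allele frequency (< `maf_min`), then
#' Hardy-Weinberg (exact p < `hwe_alpha`). A marker is attributed to the
#' first criterion it fails. LD pruning is a separate step ([ldPrune()]).
#'
#' @param x a [GenotypeData-class] object.
#' @param callrate_min minimum marker call rate (default 0.95).
#' @param maf_min minimum MAF; markers strictly below are removed (default
#'   0.05).
#' @param hwe_alpha HWE exact-test significance level (default 1e-5).
#' @param autosomes retained chromosome labels.
#' @return list with `geno` (filtered) and `report` (a `QCReport` list:
#'   in/out/excluded marker counts with per-criterion breakdown and the
#'   thresholds used).
#' @export
markerQC <- function(x, callrate_min = 0.95, maf_min = 0.05, hwe_alpha = 1e-5,
                     autosomes = as.character(1:26)) {
  stopifnot(callrate_min > 0, callrate_min <= 1, maf_min >= 0, maf_min < 0.5,
            hwe_alpha > 0, hwe_alpha < 1)
  d <- dosages(x)
  mm <- markerMap(x)
  m <- nrow(d)
  fail <- rep(NA_character_, m)
  fail[!(mm$chromosome %in% autosomes)] <- "non_autosomal"
  cr <- rowMeans(!is.na(d))
  fail[is.na(fail) & cr < callrate_min] <- "call_rate"
  p <- rowMeans(d, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.na(maf)] <- 0
  fail[is.na(fail) & maf < maf_min] <- "maf"
  todo <- which(is.na(fail))
  if (length(todo)) {
    naa <- rowSums(d[todo, , drop = FALSE] == 0L, na.rm = TRUE)
    nab <- rowSums(d[todo, , drop = FALSE] == 1L, na.rm = TRUE)
    nbb <- rowSums(d[todo, , drop = FALSE] == 2L, na.rm = TRUE)
    hp <- hweExactTest(naa, nab, nbb)
    fail[todo[hp < hwe_alpha]] <- "hwe"
  }
  keep <- is.na(fail)
  if (!any(keep))
    stop("no markers survive marker QC; review the thresholds")
  breakdown <- table(factor(fail, levels = c("non_autosomal", "call_rate",
                                             "maf", "hwe")))
  report <- list(n_markers_in = m, n_markers_out = sum(keep),
                 n_markers_excluded = sum(!keep),
                 breakdown = as.list(breakdown),
                 thresholds = list(callrate_min = callrate_min,
                                   maf_min = maf_min, hwe_alpha = hwe_alpha))
  class(report) <- "QCReport"
  list(geno = x[keep, ], report = report)
}

#' @export
print.QCReport <- function(x, ...) {
  cat(sprintf("Marker QC: %d in, %d excluded, %d retained\n",
              x$n_markers_in, x$n_markers_excluded, x$n_markers_out))
  for (nm in names(x$breakdown))
    cat(sprintf("  %-14s %d\n", nm, x$breakdown[[nm]]))
  invisible(x)
}

#' LD pruning with PLINK indep-pairwise semantics
#'
#' Within each sliding window of `window_snps` markers (step `step_snps`,
#' per chromosome), pairs with squared dosage correlation above `r2_max`
#' are resolved by removing the member with the lower MAF (tie: the marker
#' at the later position), until no intra-window pair exceeds the bound.
#'
#' @param x a [GenotypeData-class] object (markers sorted by position).
#' @param window_snps window size in SNPs (default 50).
#' @param step_snps window increment in SNPs (default 5).
#' @param r2_max maximum tolerated r-squared (default 0.50).
#' @return character vector of retained marker ids.
#' @export
ldPrune <- function(x, window_snps = 50, step_snps = 5, r2_max = 0.50) {
  d <- dosages(x)
  mm <- markerMap(x)
  p <- rowMeans(d, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  kept <- rep(TRUE, nrow(d))
  for (ch in unique(mm$chromosome)) {
    idx <- which(mm$chromosome == ch)
    m <- length(idx)
    starts <- seq(1, max(1, m), by = step_snps)
    for (s in starts) {
      win <- idx[s:min(s + window_snps - 1, m)]
      repeat {
        act <- win[kept[win]]
        if (length(act) < 2) break
        C <- suppressWarnings(cor(t(d[act, , drop = FALSE]),
                                  use = "pairwise.complete.obs"))^2
        C[!is.finite(C)] <- 0
        diag(C) <- 0
        mx <- which(C > r2_max, arr.ind = TRUE)
        if (!nrow(mx)) break
        i <- act[mx[1, 1]]; j <- act[mx[1, 2]]
        drop <- if (maf[i] < maf[j]) i
                else if (maf[j] < maf[i]) j
                else if (mm$position_bp[i] > mm$position_bp[j]) i else j
        kept[drop] <- FALSE
      }
      if (s + window_snps - 1 >= m) break
    }
  }
  rownames(d)[kept]
}
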