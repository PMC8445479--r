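#' Pairwise r-squared between two markers
#'
#' Squared Pearson correlation of dosage vectors over samples non-missing at
#' both markers (the composite, Rogers-Huff-style estimator for unphased
#' genotypes).
#'
#' @param x a [GenotypeData-class] object.
#' @param marker_i,marker_j marker ids or row indices.
#' @return r-squared in `[0, 1]`, or `NA` when fewer than 2 complete samples
#'   remain or either marker has zero variance.
#' @export
pairwiseR2 <- function(x, marker_i, marker_j) {
  d <- dosages(x)
  a <- d[marker_i, ]; b <- d[marker_j, ]
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2) return(NA_real_)
  if (sd(a[ok]) == 0 || sd(b[ok]) == 0) return(NA_real_)
  cor(a[ok], b[ok])^2
}

#' Hill-Robertson sampling correction of r-squared
#'
#' `r'^2 = (r^2 - 1/N) / (1 - 1/N)` with `N` the number of sampled
#' haplotypes (twice the sampled individuals). May be negative.
#'
#' @param r2 numeric r-squared values.
#' @param N haplotype count, `N >= 2`.
#' @return corrected values.
#' @export
hillRobertsonCorrect <- function(r2, N) {
  if (any(N < 2)) stop("N must be at least 2 haplotypes")
  (r2 - 1 / N) / (1 - 1 / N)
}

#' Per-marker LD scores
#'
#' `score(m) = 1 + sum of r2(m, m')` over markers `m'` on the same
#' chromosome within half the window of `m` (`|pos(m') - pos(m)| <=
#' window_bp / 2`); windows are centred on the scored marker and truncate at
#' chromosome edges. The self term contributes the leading 1.
#'
#' @param x a [GenotypeData-class] object.
#' @param window_bp maximum (full) window size in bp, 500 kb or 1000 kb in
#'   the analyses this package reproduces.
#' @return data.frame with `marker_id` and `score` (>= 1).
#' @export
ldScores <- function(x, window_bp = 500000) {
  d <- dosages(x)
  mm <- markerMap(x)
  half <- window_bp / 2
  score <- rep(1, nrow(d))
  for (ch in unique(mm$chromosome)) {
    idx <- which(mm$chromosome == ch)
    if (length(idx) < 2) next
    pos <- mm$position_bp[idx]
    C <- suppressWarnings(cor(t(d[idx, , drop = FALSE]),
                              use = "pairwise.complete.obs"))^2
    C[!is.finite(C)] <- 0
    inwin <- abs(outer(pos, pos, "-")) <= half
    diag(inwin) <- FALSE
    score[idx] <- 1 + rowSums(C * inwin)
  }
  data.frame(marker_id = rownames(d), score = score)
}

#' Marker pairs with distance and corrected r-squared
#'
#' Emits all same-chromosome marker pairs within `max_distance_kb`,
#' optionally restricted to pairs falling inside a common feature interval
#' (within-gene mode), with the Hill-Robertson correction applied using
#' `N = 2 x` pairwise-complete sample count.
#'
#' @param x a [GenotypeData-class] object.
#' @param max_distance_kb maximum inter-marker distance in kb (default 2500).
#' @param features optional feature table ([readFeatureTable()]); when given,
#'   only pairs with both members inside the same interval are emitted.
#' @return data.frame with `marker_i`, `marker_j`, `distance_kb`, `r2`,
#'   `r2_corrected`, `N`.
#' @export
ldPairs <- function(x, max_distance_kb = 2500, features = NULL) {
  d <- dosages(x)
  mm <- markerMap(x)
  res <- list()
  for (ch in unique(mm$chromosome)) {
    idx <- which(mm$chromosome == ch)
    if (length(idx) < 2) next
    pos <- mm$position_bp[idx]
    pairs <- which(upper.tri(diag(length(idx))), arr.ind = TRUE)
    dist_kb <- (pos[pairs[, 2]] - pos[pairs[, 1]]) / 1000
    keep <- abs(dist_kb) <= max_distance_kb
    if (!is.null(features)) {
      ft <- features[features$chromosome == ch, , drop = FALSE]
      if (!nrow(ft)) next
      inside <- function(i, j) {
        any(pos[i] >= ft$start_bp & pos[i] <= ft$end_bp &
            pos[j] >= ft$start_bp & pos[j] <= ft$end_bp)
      }
      keep <- keep & mapply(inside, pairs[, 1], pairs[, 2])
    }
    if (!any(keep)) next
    pairs <- pairs[keep, , drop = FALSE]
    dist_kb <- abs(dist_kb[keep])
    C <- suppressWarnings(cor(t(d[idx, , drop = FALSE]),
                              use = "pairwise.complete.obs"))^2
    M <- (!is.na(d[idx, , drop = FALSE])) * 1
    ncomp <- tcrossprod(M)
    r2 <- C[cbind(pairs[, 1], pairs[, 2])]
    N <- 2 * ncomp[cbind(pairs[, 1], pairs[, 2])]
    res[[ch]] <- data.frame(
      marker_i = rownames(d)[idx[pairs[, 1]]],
      marker_j = rownames(d)[idx[pairs[, 2]]],
      distance_kb = dist_kb, r2 = r2,
      r2_corrected = hillRobertsonCorrect(r2, pmax(N, 2)), N = N)
  }
  if (!length(res))
    return(data.frame(marker_i = character(0), marker_j = character(0),
                      distance_kb = numeric(0), r2 = numeric(0),
                      r2_corrected = numeric(0), N = numeric(0)))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[is.finite(out$r2), , drop = FALSE]
}

#' Wilcoxon rank-sum comparison of two LD-score distributions
#'
#' Two-sided rank-sum test with midranks for ties: exact when the combined
#' sample size is at most 20 and there are no ties, normal approximation
#' with tie and continuity correction otherwise.
#'
#' @param scores_a,scores_b numeric samples (each length >= 1).
#' @return list with `statistic` (W) and `p_value`.
#' @export
wilcoxonRankSum <- function(scores_a, scores_b) {
  exact <- (length(scores_a) + length(scores_b)) <= 20
  wt <- suppressWarnings(wilcox.test(scores_a, scores_b, exact = exact,
                                     correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Fit the Sved-type LD-decay curve
#'
#' Nonlinear least squares of `y = 1 / (1 + 4 beta d)` on corrected
#' r-squared versus distance (kb), by Levenberg-Marquardt. Pairs with
#' non-positive corrected r-squared or distance beyond `max_distance_kb`
#' are excluded before fitting (the sampling correction makes exact zeros
#' and negatives uninformative). The start value inverts the model at the
#' distance-weighted mean point; convergence at relative parameter change
#' below 1e-10 or 200 iterations. The standard error comes from the
#' Gauss-Newton approximation and the 95% CI is `beta +/- 1.96 se`.
#'
#' @param pairs data.frame from [ldPairs()] (needs `distance_kb` and
#'   `r2_corrected`).
#' @param max_distance_kb maximum distance retained (default 2500).
#' @param origin label stored in the result.
#' @param positive_only drop pairs with corrected r-squared <= 0 before
#'   fitting (default TRUE, the protocol used on Hill-Robertson-corrected
#'   empirical r-squared). Note this selection biases the fit when applied
#'   to symmetric-noise data whose truth is near zero at long range; set
#'   FALSE for calibration studies on synthetic pairs.
#' @return an [LDDecayFit-class] object.
#' @export
fitLdDecay <- function(pairs, max_distance_kb = 2500, origin = "all",
                       positive_only = TRUE) {
  d <- pairs$distance_kb
  y <- pairs$r2_corrected
  keep <- is.finite(d) & is.finite(y) & d <= max_distance_kb
  if (positive_only) keep <- keep & y > 0
  d <- d[keep]; y <- y[keep]
  if (length(d) < 10) stop("need at least 10 usable pairs to fit LD decay")
  d0 <- sum(d * d) / sum(d)
  y0 <- sum(y * d) / sum(d)
  beta0 <- max((1 / min(max(y0, 1e-6), 1 - 1e-9) - 1) / (4 * d0), 1e-6)
  fit <- minpack.lm::nlsLM(
    y ~ 1 / (1 + 4 * beta * d),
    data = data.frame(d = d, y = y),
    start = list(beta = beta0),
    lower = 1e-9,
    control = minpack.lm::nls.lm.control(maxiter = 200, ptol = 1e-10))
  if (!fit$convInfo$isConv && fit$convInfo$stopCode %in% c(5L))
    stop(sprintf("LD-decay fit did not converge (last beta %.6g)",
                 coef(fit)[["beta"]]))
  beta <- coef(fit)[["beta"]]
  se <- summary(fit)$coefficients["beta", "Std. Error"]
  rv <- summary(fit)$sigma^2
  new("LDDecayFit", beta = beta, se_beta = se,
      ci95 = c(beta - 1.96 * se, beta + 1.96 * se),
      n_pairs = length(d), origin = origin, residual_variance = rv)
}
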