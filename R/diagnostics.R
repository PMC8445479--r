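#' Raw diagnostic statistics around a focal marker
#'
#' For every marker within `flank_bp` of the focal marker (same chromosome):
#' truncated Weir-Cockerham F_ST between the two origins, the average
#' observed heterozygosity of the two populations
#' `av_ho = (Ho_pop1 + Ho_pop2) / 2` and their difference
#' `d_ho = Ho_pop1 - Ho_pop2`, with Ho the heterozygote fraction among
#' non-missing genotypes. Population 1 is the alphabetically first origin
#' label. Markers with no genotypes in one population are excluded (flagged
#' in the `n_excluded` attribute).
#'
#' @param x a [GenotypeData-class] object with a two-level `origin`.
#' @param focal_marker marker id.
#' @param flank_bp half-width of the window (default 1 Mb).
#' @return data.frame with `marker_id`, `position_bp`, `fst`, `av_ho`,
#'   `d_ho`; attribute `focal_position`.
#' @export
localDiagnosticStats <- function(x, focal_marker, flank_bp = 1000000) {
  mm <- markerMap(x)
  fi <- match(focal_marker, mm$marker_id)
  if (is.na(fi)) stop(sprintf("focal marker %s not found", focal_marker))
  ch <- mm$chromosome[fi]; pos <- mm$position_bp[fi]
  sel <- mm$chromosome == ch &
    mm$position_bp >= pos - flank_bp & mm$position_bp <= pos + flank_bp
  if (sum(sel) < 3) stop("fewer than 3 markers in the diagnostic window")
  sub <- x[sel, ]
  d <- dosages(sub)
  origin <- as.character(sampleInfo(sub)$origin)
  labs <- sort(unique(origin[!is.na(origin)]))
  stopifnot(length(labs) == 2)
  ho <- function(lab) {
    dd <- d[, origin == lab & !is.na(origin), drop = FALSE]
    het <- rowSums(dd == 1L, na.rm = TRUE)
    tot <- rowSums(!is.na(dd))
    ifelse(tot > 0, het / tot, NA_real_)
  }
  ho1 <- ho(labs[1]); ho2 <- ho(labs[2])
  fst <- fstPerSnp(sub)$fst
  out <- data.frame(marker_id = rownames(d),
                    position_bp = markerMap(sub)$position_bp,
                    fst = fst, av_ho = (ho1 + ho2) / 2, d_ho = ho1 - ho2)
  keep <- !is.na(out$av_ho)
  excl <- sum(!keep)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "focal_position") <- pos
  attr(out, "n_excluded") <- excl
  out
}

#' Local (loess-type) tricube smoother
#'
#' Degree-1 local regression with tricube weights over the
#' `ceiling(span * n)` nearest neighbours of each point, no robustness
#' iterations, evaluated at each input x.
#'
#' @param x numeric predictor (at least 2 distinct values).
#' @param y numeric response.
#' @param span smoothing parameter in (0, 1]; default 0.21.
#' @return fitted values at each input point.
#' @export
loessSmooth <- function(x, y, span = 0.21) {
  n <- length(x)
  stopifnot(length(y) == n, span > 0, span <= 1)
  if (length(unique(x)) < 2) stop("need at least 2 distinct x values")
  q <- max(2, ceiling(span * n))
  fit <- numeric(n)
  for (i in seq_len(n)) {
    dd <- abs(x - x[i])
    h <- sort(dd, partial = q)[q]
    if (h == 0) h <- max(dd[dd > 0][1], .Machine$double.eps)
    w <- (1 - pmin(dd / h, 1)^3)^3
    use <- w > 0
    if (sum(use) < 2) { use <- dd <= h * (1 + 1e-9); w[use] <- pmax(w[use], 1e-9) }
    xw <- x[use]; yw <- y[use]; ww <- w[use]
    sw <- sum(ww); sx <- sum(ww * xw); sy <- sum(ww * yw)
    sxx <- sum(ww * xw^2); sxy <- sum(ww * xw * yw)
    det <- sw * sxx - sx^2
    if (abs(det) < 1e-300) {
      fit[i] <- sy / sw
    } else {
      b <- (sw * sxy - sx * sy) / det
      a <- (sy - b * sx) / sw
      fit[i] <- a + b * x[i]
    }
  }
  fit
}

#' Diagnostic profile with smoothed curves
#'
#' Runs [localDiagnosticStats()] and adds loess-smoothed columns
#' (`fst_smooth`, `av_ho_smooth`, `d_ho_smooth`) at the given span.
#'
#' @inheritParams localDiagnosticStats
#' @param span loess smoothing parameter (default 0.21).
#' @return the profile data.frame with smoothed columns and the
#'   `focal_position` attribute.
#' @export
diagnosticProfile <- function(x, focal_marker, flank_bp = 1000000,
                              span = 0.21) {
  prof <- localDiagnosticStats(x, focal_marker, flank_bp)
  prof$fst_smooth <- loessSmooth(prof$position_bp, prof$fst, span)
  prof$av_ho_smooth <- loessSmooth(prof$position_bp, prof$av_ho, span)
  prof$d_ho_smooth <- loessSmooth(prof$position_bp, prof$d_ho, span)
  prof
}

#' Classify the selective process around a focal marker
#'
#' Quantitative operationalization of the characteristic local-adaptation
#' pattern: the label is `"local_adaptation"` iff (a) the smoothed F_ST
#' curve attains its window maximum within `colocate_bp` of the focal
#' position, (b) the smoothed |d_ho| curve attains its maximum within
#' `colocate_bp` of the focal position, and (c) the smoothed av_ho at the
#' focal position lies below the window median of smoothed av_ho (the
#' diversity dip). Otherwise `"not_local_adaptation"`; `"inconclusive"`
#' when any curve is undefined. The supporting margins are returned as
#' metrics.
#'
#' @param profile data.frame from [diagnosticProfile()] (needs the smoothed
#'   columns and the `focal_position` attribute, or pass `focal_position`).
#' @param focal_position focal bp position (defaults to the attribute).
#' @param colocate_bp co-location tolerance (default 100 kb).
#' @return list with `label` and `metrics` (peak offsets in bp and the
#'   av_ho margin below the median).
#' @export
classifySelectiveProcess <- function(profile, focal_position = NULL,
                                     colocate_bp = 100000) {
  if (is.null(focal_position)) focal_position <- attr(profile, "focal_position")
  stopifnot(!is.null(focal_position))
  sm <- profile[, c("fst_smooth", "av_ho_smooth", "d_ho_smooth")]
  if (any(!is.finite(as.matrix(sm))))
    return(list(label = "inconclusive", metrics = list()))
  pos <- profile$position_bp
  fst_peak <- pos[which.max(profile$fst_smooth)]
  dho_peak <- pos[which.max(abs(profile$d_ho_smooth))]
  i_focal <- which.min(abs(pos - focal_position))
  avho_focal <- profile$av_ho_smooth[i_focal]
  avho_med <- median(profile$av_ho_smooth)
  metrics <- list(fst_peak_offset_bp = abs(fst_peak - focal_position),
                  dho_peak_offset_bp = abs(dho_peak - focal_position),
                  avho_margin = avho_med - avho_focal)
  ok <- metrics$fst_peak_offset_bp <= colocate_bp &&
    metrics$dho_peak_offset_bp <= colocate_bp &&
    metrics$avho_margin > 0
  list(label = if (ok) "local_adaptation" else "not_local_adaptation",
       metrics = metrics)
}
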