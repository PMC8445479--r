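#' Features near a marker
#'
#' Positional candidate lookup: all features on the marker's chromosome
#' whose gap to the marker is at most `flank_bp` (inclusive bound), sorted
#' by distance. The distance is 0 when the marker lies inside the feature
#' interval (1-based inclusive), otherwise the gap to the nearest edge,
#' `min(|pos - start|, |pos - end|)`.
#'
#' @param chromosome,position_bp marker location.
#' @param features feature table ([readFeatureTable()]).
#' @param flank_bp search radius in bp (default 500 kb).
#' @param marker_id optional id recorded in the result.
#' @return data.frame of hits with `marker_id`, feature columns and
#'   `distance_bp`, sorted by increasing distance (empty when the chromosome
#'   is absent from the table).
#' @export
featuresNearMarker <- function(chromosome, position_bp, features,
                               flank_bp = 500000, marker_id = NA_character_) {
  ft <- features[features$chromosome == as.character(chromosome), , drop = FALSE]
  if (!nrow(ft))
    return(cbind(data.frame(marker_id = character(0)), features[0, ],
                 distance_bp = numeric(0)))
  inside <- position_bp >= ft$start_bp & position_bp <= ft$end_bp
  gap <- pmin(abs(position_bp - ft$start_bp), abs(position_bp - ft$end_bp))
  dist <- ifelse(inside, 0, gap)
  keep <- dist <= flank_bp
  out <- cbind(data.frame(marker_id = marker_id), ft[keep, , drop = FALSE],
               distance_bp = dist[keep])
  out <- out[order(out$distance_bp, out$feature_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
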