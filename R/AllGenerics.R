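#' Dosage matrix accessor
#'
#' @param x a [GenotypeData-class] object.
#' @return integer matrix, markers x samples, counting the B allele (NA =
#'   missing).
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname dosages
#' @export
setMethod("dosages", "GenotypeData", function(x)
  SummarizedExperiment::assay(x, "dosage"))

#' Marker map accessor
#'
#' @param x a [GenotypeData-class] object.
#' @return data.frame with columns `marker_id`, `chromosome`, `position_bp`,
#'   `allele_a`, `allele_b`, in storage (sorted) order.
#' @export
setGeneric("markerMap", function(x) standardGeneric("markerMap"))

#' @rdname markerMap
#' @export
setMethod("markerMap", "GenotypeData", function(x) {
  rd <- SummarizedExperiment::rowData(x)
  cbind(data.frame(marker_id = rownames(x)),
        as.data.frame(rd, row.names = NULL))
})

#' Sample table accessor
#'
#' @param x a [GenotypeData-class] object.
#' @return data.frame with a `sample_id` column plus whatever annotation is
#'   present (`origin`, `region`, `herd`, `coord_x`, `coord_y`).
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))

#' @rdname sampleInfo
#' @export
setMethod("sampleInfo", "GenotypeData", function(x) {
  cd <- SummarizedExperiment::colData(x)
  cbind(data.frame(sample_id = colnames(x)),
        as.data.frame(cd, row.names = NULL))
})

#' Drift (kinship) matrix accessor
#'
#' @param x a [PopTree-class] object.
#' @return the populations x populations drift covariance matrix `F`.
#' @export
setGeneric("driftMatrix", function(x) standardGeneric("driftMatrix"))

#' @rdname driftMatrix
#' @export
setMethod("driftMatrix", "PopTree", function(x) x@F)
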