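#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames rowData colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats median pchisq qchisq pnorm var cor sd quantile runif rnorm
#'   rbeta rbinom setNames complete.cases optimize p.adjust dist wilcox.test
#'   lm coef qnorm
#' @importFrom utils read.table write.table head
NULL

#' GenotypeData: diploid SNP genotypes with marker and sample annotation
#'
#' The central container of the package. It extends
#' [SummarizedExperiment::SummarizedExperiment] with one assay, `"dosage"`:
#' an integer matrix of markers (rows) by samples (columns) counting copies
#' of the B allele (0, 1 or 2), with `NA` for missing genotypes. Marker
#' annotation (chromosome, base-pair position, alleles) lives in `rowData`;
#' sample annotation (origin, region, herd, coordinates) lives in `colData`.
#'
#' Conventions fixed across the package:
#' * the counted (B) allele is the second allele column of a BIM record;
#' * positions are 1-based inclusive at I/O boundaries, window arithmetic
#'   internally is half-open `[start, end)`;
#' * markers are stored sorted by (chromosome, position);
#' * only autosome labels (by default `"1"`..`"26"`, Ovis aries) are retained
#'   by the readers.
#'
#' @seealso [GenotypeData()] for construction, [readPlinkText()],
#'   [readPlinkBinary()], [simulateGenotypes()].
#' @export
setClass("GenotypeData", contains = "SummarizedExperiment")

.validGenotypeData <- function(object) {
  msg <- NULL
  if (!("dosage" %in% SummarizedExperiment::assayNames(object)))
    msg <- c(msg, "assay 'dosage' is required")
  else {
    d <- SummarizedExperiment::assay(object, "dosage")
    v <- d[!is.na(d)]
    if (length(v) && !all(v %in% c(0L, 1L, 2L)))
      msg <- c(msg, "non-missing dosages must be 0, 1 or 2")
  }
  rd <- SummarizedExperiment::rowData(object)
  need <- c("chromosome", "position_bp", "allele_a", "allele_b")
  miss <- setdiff(need, colnames(rd))
  if (length(miss))
    msg <- c(msg, paste0("rowData lacks column(s): ", paste(miss, collapse = ", ")))
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "marker ids (rownames) must be unique")
  if (!length(msg) && nrow(object) > 1) {
    ord <- order(.chromOrder(rd$chromosome), rd$position_bp)
    if (!identical(ord, seq_len(nrow(object))))
      msg <- c(msg, "markers must be sorted by (chromosome, position_bp)")
    if (any(rd$position_bp < 1))
      msg <- c(msg, "position_bp must be >= 1")
  }
  if (is.null(msg)) TRUE else msg
}
setValidity("GenotypeData", .validGenotypeData)

# chromosome labels sort numerically when they look numeric, else lexical
.chromOrder <- function(chr) {
  n <- suppressWarnings(as.numeric(chr))
  if (anyNA(n)) match(chr, unique(chr)) else n
}

#' Construct a GenotypeData object
#'
#' @param dosage integer matrix, markers x samples, entries 0/1/2/NA counting
#'   the B allele.
#' @param markerMap data.frame with columns `marker_id`, `chromosome`
#'   (character), `position_bp` (1-based), `allele_a`, `allele_b`; one row per
#'   row of `dosage`.
#' @param sampleInfo optional data.frame with a `sample_id` column and any of
#'   `origin` (`"island"`/`"mainland"`), `region`, `herd`, `coord_x`,
#'   `coord_y`. Defaults to ids taken from `colnames(dosage)`.
#' @return a [GenotypeData-class] object with markers sorted by
#'   (chromosome, position).
#' @examples
#' d <- matrix(c(0L, 1L, 2L, 1L), 2, 2,
#'             dimnames = list(c("m1", "m2"), c("s1", "s2")))
#' mm <- data.frame(marker_id = c("m1", "m2"), chromosome = "1",
#'                  position_bp = c(100L, 200L),
#'                  allele_a = "A", allele_b = "B")
#' g <- GenotypeData(d, mm)
#' @export
GenotypeData <- function(dosage, markerMap, sampleInfo = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  stopifnot(nrow(dosage) == nrow(markerMap))
  markerMap$chromosome <- as.character(markerMap$chromosome)
  markerMap$position_bp <- as.integer(markerMap$position_bp)
  if (is.null(rownames(dosage))) rownames(dosage) <- markerMap$marker_id
  if (is.null(sampleInfo)) {
    if (is.null(colnames(dosage)))
      colnames(dosage) <- sprintf("sample_%d", seq_len(ncol(dosage)))
    sampleInfo <- data.frame(sample_id = colnames(dosage))
  }
  stopifnot(nrow(sampleInfo) == ncol(dosage))
  if (anyDuplicated(sampleInfo$sample_id))
    stop("sample ids must be unique")
  colnames(dosage) <- sampleInfo$sample_id
  ord <- order(.chromOrder(markerMap$chromosome), markerMap$position_bp)
  dosage <- dosage[ord, , drop = FALSE]
  markerMap <- markerMap[ord, , drop = FALSE]
  rownames(dosage) <- markerMap$marker_id
  rd <- S4Vectors::DataFrame(markerMap[setdiff(colnames(markerMap), "marker_id")],
                             row.names = markerMap$marker_id)
  cd <- S4Vectors::DataFrame(sampleInfo[setdiff(colnames(sampleInfo), "sample_id")],
                             row.names = sampleInfo$sample_id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = dosage), rowData = rd, colData = cd)
  new("GenotypeData", se)
}

#' @describeIn GenotypeData-class compact display
#' @param object a `GenotypeData`
#' @export
setMethod("show", "GenotypeData", function(object) {
  d <- SummarizedExperiment::assay(object, "dosage")
  chr <- unique(as.character(SummarizedExperiment::rowData(object)$chromosome))
  cat(sprintf("GenotypeData: %d markers x %d samples on %d chromosome(s)\n",
              nrow(object), ncol(object), length(chr)))
  cat(sprintf("  missing genotypes: %.3f%%\n", 100 * mean(is.na(d))))
  org <- sampleInfo(object)$origin
  if (!is.null(org))
    cat("  origin: ", paste(sprintf("%s=%d", names(table(org)), table(org)),
                            collapse = ", "), "\n", sep = "")
})

#' Population tree with drift (kinship) matrix
#'
#' Holds a rooted population tree (an [ape::phylo] object), the population
#' labels at its leaves and the drift covariance matrix `F` whose entry
#' `(i, j)` is the branch length shared by populations `i` and `j` on the
#' path from the root; the diagonal is each population's total drift from
#' the root. `F` is the kinship matrix consumed by [flkTest()].
#'
#' @slot tree a rooted `phylo` object (branch lengths are drift units).
#' @slot F numeric matrix, populations x populations.
#' @slot labels character vector of population labels.
#' @export
setClass("PopTree",
         representation(tree = "ANY", F = "matrix", labels = "character"))

setValidity("PopTree", function(object) {
  msg <- NULL
  if (!is.matrix(object@F) || nrow(object@F) != length(object@labels))
    msg <- c(msg, "F must be square with one row per population label")
  if (length(object@labels) >= 1 && any(diag(object@F) < 0))
    msg <- c(msg, "diagonal drift must be non-negative")
  ev <- eigen(object@F, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8)) msg <- c(msg, "F must be positive semi-definite")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn PopTree-class compact display
#' @param object a `PopTree`
#' @export
setMethod("show", "PopTree", function(object) {
  cat(sprintf("PopTree with %d populations: %s\n", length(object@labels),
              paste(object@labels, collapse = ", ")))
  cat("  drift (diag of F): ",
      paste(sprintf("%.4g", diag(object@F)), collapse = ", "), "\n", sep = "")
})

#' Fitted LD-decay curve
#'
#' Result of [fitLdDecay()]: the decline-rate coefficient `beta` of the
#' Sved-type curve `r2 = 1 / (1 + 4 * beta * d)` (distance `d` in kb), its
#' Gauss-Newton standard error, a 95% Wald confidence interval, the number of
#' marker pairs used, the residual variance and an origin label.
#'
#' @slot beta numeric decline rate per kb.
#' @slot se_beta numeric standard error.
#' @slot ci95 numeric length-2 vector (low, high).
#' @slot n_pairs integer number of pairs fitted.
#' @slot origin character label.
#' @slot residual_variance numeric.
#' @export
setClass("LDDecayFit",
         representation(beta = "numeric", se_beta = "numeric",
                        ci95 = "numeric", n_pairs = "integer",
                        origin = "character", residual_variance = "numeric"))

#' @describeIn LDDecayFit-class compact display
#' @param object an `LDDecayFit`
#' @export
setMethod("show", "LDDecayFit", function(object) {
  cat(sprintf("LD decay fit (%s): beta = %.4f +/- %.5f per kb, CI95 [%.4f, %.4f], %d pairs\n",
              object@origin, object@beta, object@se_beta,
              object@ci95[1], object@ci95[2], object@n_pairs))
})
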