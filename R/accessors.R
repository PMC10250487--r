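#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame
NULL

#' Construct a SpectraBlock from a samples-by-bins matrix
#'
#' @param intensity numeric matrix, samples in rows, bins in columns, in
#'   increasing m/z order.
#' @param lo,hi,width binning parameters in Da; `width` must divide
#'   `hi - lo` exactly (the defaults give the 5500-bin axis).
#' @param sampleIds character sample identifiers (defaults to rownames).
#' @param class optional class label per sample.
#' @return A [SpectraBlock-class] object.
#' @export
SpectraBlock <- function(intensity, lo = 100, hi = 1200, width = 0.2,
                         sampleIds = rownames(intensity), class = NULL) {
  intensity <- as.matrix(intensity)
  if (is.null(sampleIds))
    sampleIds <- sprintf("S%03d", seq_len(nrow(intensity)))
  nb <- round((hi - lo) / width)
  labs <- binLabelsFor(lo, hi, width)
  rd <- DataFrame(binLabel = labs,
                  loEdge = lo + (seq_len(nb) - 1L) * width)
  cd <- DataFrame(row.names = sampleIds)
  if (!is.null(class)) cd$class <- factor(class)
  a <- t(intensity)
  dimnames(a) <- list(format(labs, trim = TRUE), sampleIds)
  new("SpectraBlock",
      SummarizedExperiment(assays = list(intensity = a),
                           rowData = rd, colData = cd),
      binning = list(lo = lo, hi = hi, width = width))
}

#' Construct an ElementBlock from a samples-by-elements matrix
#'
#' @param concentration numeric matrix, samples in rows, elements in
#'   columns (named).
#' @param belowLOD optional logical mask of the same shape; defaults to
#'   `concentration == 0` (below-LOD values are substituted by 0).
#' @param sampleIds character sample identifiers.
#' @param class optional class label per sample.
#' @return An [ElementBlock-class] object.
#' @export
ElementBlock <- function(concentration, belowLOD = NULL,
                         sampleIds = rownames(concentration), class = NULL) {
  concentration <- as.matrix(concentration)
  if (is.null(sampleIds))
    sampleIds <- sprintf("S%03d", seq_len(nrow(concentration)))
  if (is.null(belowLOD)) belowLOD <- concentration == 0
  storage.mode(belowLOD) <- "logical"
  cd <- DataFrame(row.names = sampleIds)
  if (!is.null(class)) cd$class <- factor(class)
  a <- t(concentration); m <- t(belowLOD)
  dimnames(a) <- dimnames(m) <- list(colnames(concentration), sampleIds)
  new("ElementBlock",
      SummarizedExperiment(assays = list(concentration = a, belowLOD = m),
                           colData = cd))
}

#' @rdname intensities
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' Samples-by-features matrix of a block
#'
#' Returns the modelling orientation (samples in rows), the transpose of
#' the stored assay.
#' @param x a SpectraBlock or ElementBlock.
#' @export
setMethod("intensities", "SpectraBlock", function(x) t(assay(x, "intensity")))

#' @rdname intensities
#' @export
setMethod("intensities", "ElementBlock",
          function(x) t(assay(x, "concentration")))

#' @rdname sampleIds
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' Sample identifiers of a block
#' @param x a SpectraBlock or ElementBlock.
#' @export
setMethod("sampleIds", "SummarizedExperiment", function(x) colnames(x))

#' @rdname classLabels
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' Class labels attached to a block (or NULL)
#' @param x a SpectraBlock or ElementBlock.
#' @export
setMethod("classLabels", "SummarizedExperiment", function(x) x$class)

#' @rdname binLabels
#' @export
setGeneric("binLabels", function(x) standardGeneric("binLabels"))

#' Bin labels (bin centres rounded to 0.1 Da) of a SpectraBlock
#' @param x a SpectraBlock.
#' @export
setMethod("binLabels", "SpectraBlock", function(x) rowData(x)$binLabel)

#' @rdname elementNames
#' @export
setGeneric("elementNames", function(x) standardGeneric("elementNames"))

#' Element names of an ElementBlock
#' @param x an ElementBlock.
#' @export
setMethod("elementNames", "ElementBlock", function(x) rownames(x))

#' @rdname lodMask
#' @export
setGeneric("lodMask", function(x) standardGeneric("lodMask"))

#' Below-LOD mask of an ElementBlock (samples x elements)
#' @param x an ElementBlock.
#' @export
setMethod("lodMask", "ElementBlock", function(x) t(assay(x, "belowLOD")))

#' @rdname fusedMatrix
#' @export
setGeneric("fusedMatrix", function(x) standardGeneric("fusedMatrix"))

#' Fused samples-by-features matrix of a FusedMatrix
#' @param x a FusedMatrix.
#' @export
setMethod("fusedMatrix", "FusedMatrix", function(x) x@fused)

#' @rdname provenance
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' Per-feature block provenance of a FusedMatrix
#' @param x a FusedMatrix.
#' @export
setMethod("provenance", "FusedMatrix", function(x) x@provenance)

#' @rdname scores
#' @export
setGeneric("scores", function(x, ...) standardGeneric("scores"))

#' Score matrix of a LatentModel
#' @param x a LatentModel.
#' @param ... unused.
#' @export
setMethod("scores", "LatentModel", function(x, ...) x@scores)

#' @rdname loadings2
#' @export
setGeneric("modelLoadings", function(x, ...) standardGeneric("modelLoadings"))

#' Loading matrix of a LatentModel
#' @param x a LatentModel.
#' @param ... unused.
#' @export
setMethod("modelLoadings", "LatentModel", function(x, ...) x@loadings)

#' @rdname confusionMatrix
#' @export
setGeneric("confusionMatrix", function(x) standardGeneric("confusionMatrix"))

#' Confusion matrix (with Outlier column) of a CVResult
#' @param x a CVResult.
#' @export
setMethod("confusionMatrix", "CVResult", function(x) x@confusion)

#' @rdname overallRate
#' @export
setGeneric("overallRate", function(x) standardGeneric("overallRate"))

#' Overall correct-classification rate (%) of a CVResult
#' @param x a CVResult.
#' @export
setMethod("overallRate", "CVResult", function(x) x@overallRate)

#' @rdname perClassRate
#' @export
setGeneric("perClassRate", function(x) standardGeneric("perClassRate"))

#' Per-class correct-classification rates (%) of a CVResult
#' @param x a CVResult.
#' @export
setMethod("perClassRate", "CVResult", function(x) x@perClassRate)

# bin labels for a uniform axis: centres rounded to 1 decimal
binLabelsFor <- function(lo, hi, width) {
  nb <- round((hi - lo) / width)
  round(lo + (seq_len(nb) - 0.5) * width, 1)
}
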