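#' @import methods
#' @importFrom stats sd quantile qnorm pf qf rlnorm runif predict p.adjust
#'   kruskal.test wilcox.test setNames
#' @importFrom utils read.csv write.csv head combn
NULL

#' SpectraBlock: binned mass-spectral fingerprints
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding a samples-by-bins
#' intensity block from an ambient MS fingerprinting platform. Rows are
#' uniform-width m/z bins (default 0.2 Da over m/z 100--1200, i.e. 5500
#' bins), columns are samples. Bin edges and labels (bin centres rounded to
#' one decimal, the "ion bin category" convention) live in `rowData`; the
#' optional class label lives in `colData$class`.
#'
#' @slot binning list with elements `lo`, `hi`, `width` (Da).
#' @export
setClass("SpectraBlock",
  contains = "SummarizedExperiment",
  slots = c(binning = "list"))

setValidity("SpectraBlock", function(object) {
  b <- object@binning
  if (!all(c("lo", "hi", "width") %in% names(b)))
    return("binning must contain lo, hi, width")
  nb <- (b$hi - b$lo) / b$width
  if (abs(nb - round(nb)) > 1e-8)
    return("bin width must divide (hi - lo) exactly")
  if (nrow(object) != round(nb))
    return(sprintf("expected %d bins, found %d", round(nb), nrow(object)))
  if (any(assay(object) < 0)) return("negative intensities")
  labs <- rowData(object)$binLabel
  if (anyDuplicated(labs)) return("bin labels must be unique")
  TRUE
})

#' ElementBlock: ICP-MS element concentration profiles
#'
#' A [SummarizedExperiment::SummarizedExperiment] with a samples-by-elements
#' concentration block (assay `"concentration"`, ng/g scale) and a parallel
#' logical below-LOD mask (assay `"belowLOD"`). Rows are elements, columns
#' samples; `colData$class` optionally carries the group label.
#'
#' @export
setClass("ElementBlock", contains = "SummarizedExperiment")

setValidity("ElementBlock", function(object) {
  if (!all(c("concentration", "belowLOD") %in% assayNames(object)))
    return("assays 'concentration' and 'belowLOD' are required")
  if (any(assay(object, "concentration") < 0))
    return("concentrations must be non-negative")
  if (!is.logical(assay(object, "belowLOD")))
    return("belowLOD mask must be logical")
  TRUE
})

#' PeakList: a single centroided spectrum
#'
#' Pairs of (m/z, intensity) within a half-open acquisition range
#' `[lo, hi)`.
#'
#' @slot mz numeric m/z values (Da).
#' @slot intensity non-negative intensities.
#' @slot lo,hi acquisition range (Da).
#' @export
setClass("PeakList", slots = c(mz = "numeric", intensity = "numeric",
                               lo = "numeric", hi = "numeric"))

setValidity("PeakList", function(object) {
  if (length(object@mz) != length(object@intensity))
    return("mz and intensity lengths differ")
  if (any(object@intensity < 0)) return("intensities must be non-negative")
  TRUE
})

#' @rdname PeakList-class
#' @param mz,intensity numeric vectors of equal length.
#' @param lo,hi acquisition range in Da.
#' @export
PeakList <- function(mz, intensity, lo = 100, hi = 1200) {
  o <- order(mz)
  new("PeakList", mz = as.numeric(mz[o]), intensity = as.numeric(intensity[o]),
      lo = lo, hi = hi)
}

#' BlockCompression: a fitted PCA compression of one data block
#'
#' Stores everything needed to map new samples of the same block into the
#' retained score space: centering and scaling vectors, orthonormal
#' loadings, and the per-component explained-variance fractions.
#'
#' @slot blockName character.
#' @slot center,scale numeric vectors (length p).
#' @slot scalingMode "none", "uv" or "pareto".
#' @slot loadings p x k orthonormal matrix.
#' @slot varExplained length-k explained variance fractions.
#' @slot k retained components.
#' @slot threshold cumulative-variance threshold used (NA if k forced).
#' @export
setClass("BlockCompression",
  slots = c(blockName = "character", center = "numeric", scale = "numeric",
            scalingMode = "character", loadings = "matrix",
            varExplained = "numeric", k = "integer", threshold = "numeric"))

setValidity("BlockCompression", function(object) {
  if (object@k < 1L) return("k must be >= 1")
  if (ncol(object@loadings) != object@k) return("loadings/k mismatch")
  g <- crossprod(object@loadings)
  if (max(abs(g - diag(object@k))) > 1e-6)
    return("loadings columns must be orthonormal")
  TRUE
})

#' FusedMatrix: a fitted low- or mid-level fusion of several blocks
#'
#' Carries the fused samples-by-features matrix, exact per-column block
#' provenance, and the fitted per-block transforms (min-max scalers for
#' low-level fusion, [BlockCompression-class] objects for mid-level) needed
#' to project held-out samples without re-fitting.
#'
#' @slot fused numeric matrix, samples x features.
#' @slot provenance data.frame with one row per fused column: `block`,
#'   `feature`.
#' @slot level "low" or "mid".
#' @slot transforms named list of per-block fitted transforms.
#' @slot weighting per-block score weighting mode ("none" or "variance").
#' @export
setClass("FusedMatrix",
  slots = c(fused = "matrix", provenance = "data.frame", level = "character",
            transforms = "list", weighting = "character"))

setValidity("FusedMatrix", function(object) {
  if (nrow(object@provenance) != ncol(object@fused))
    return("provenance must cover every fused column exactly once")
  if (!object@level %in% c("low", "mid")) return("level must be low or mid")
  if (!setequal(unique(object@provenance$block), names(object@transforms)))
    return("transforms must be named after the fused blocks")
  TRUE
})

#' LatentModel: scores/loadings container for PCA, PLS-DA and OPLS-DA
#'
#' @slot kind "PCA", "PLSDA" or "OPLSDA".
#' @slot center,scale preprocessing vectors applied to X.
#' @slot scalingMode "none", "uv" or "pareto".
#' @slot scores n x a score matrix T (training).
#' @slot loadings p x a loading matrix P.
#' @slot weights p x a weight matrix W (PLS family; empty for PCA).
#' @slot yloadings a x m Y-loading matrix C (PLS family).
#' @slot orthoScores,orthoLoadings,orthoWeights orthogonal-component
#'   matrices (OPLS only; zero-column otherwise).
#' @slot coef p x m regression coefficient matrix (PLS family).
#' @slot classes factor levels of the response (discriminant models).
#' @slot yMeans column means of the one-hot Y (discriminant models).
#' @slot R2X,R2Y,Q2 cumulative variance bookkeeping (NA when not computed).
#' @slot varExplained per-component R2X fractions.
#' @slot trainResid per-row residual distance of the training data (for
#'   distance-to-model outlier limits).
#' @export
setClass("LatentModel",
  slots = c(kind = "character", center = "numeric", scale = "numeric",
            scalingMode = "character", scores = "matrix", loadings = "matrix",
            weights = "matrix", yloadings = "matrix",
            orthoScores = "matrix", orthoLoadings = "matrix",
            orthoWeights = "matrix", coef = "matrix", classes = "character",
            yMeans = "numeric", R2X = "numeric", R2Y = "numeric",
            Q2 = "numeric", varExplained = "numeric", trainResid = "numeric"))

setValidity("LatentModel", function(object) {
  if (!object@kind %in% c("PCA", "PLSDA", "OPLSDA"))
    return("kind must be PCA, PLSDA or OPLSDA")
  if (ncol(object@scores) != ncol(object@loadings))
    return("scores/loadings component mismatch")
  for (s in c("R2X", "R2Y")) {
    v <- slot(object, s)
    if (!is.na(v) && (v < -1e-9 || v > 1 + 1e-9))
      return(sprintf("%s must lie in [0,1]", s))
  }
  TRUE
})

#' CVResult: cross-validated classification summary
#'
#' @slot confusion true-class x predicted-class count matrix with a final
#'   `Outlier` column.
#' @slot perClassRate per-class correct-classification rates (%).
#' @slot overallRate overall correct-classification rate (%); outlier-flagged
#'   predictions count as incorrect.
#' @slot foldAssign integer fold assignment per sample.
#' @slot predictions per-sample predicted label (or "Outlier"), in input
#'   order.
#' @slot seed RNG seed used for the partition.
#' @export
setClass("CVResult",
  slots = c(confusion = "matrix", perClassRate = "numeric",
            overallRate = "numeric", foldAssign = "integer",
            predictions = "character", seed = "integer"))

setValidity("CVResult", function(object) {
  if (colnames(object@confusion)[ncol(object@confusion)] != "Outlier")
    return("last confusion column must be 'Outlier'")
  if (object@overallRate < 0 || object@overallRate > 100)
    return("overallRate must be a percentage")
  TRUE
})

setMethod("show", "SpectraBlock", function(object) {
  b <- object@binning
  cat(sprintf("SpectraBlock: %d samples x %d bins (m/z %g-%g, %g Da)\n",
              ncol(object), nrow(object), b$lo, b$hi, b$width))
  if (!is.null(object$class))
    cat("  classes:", paste(levels(factor(object$class)), collapse = ", "), "\n")
})

setMethod("show", "ElementBlock", function(object) {
  cat(sprintf("ElementBlock: %d samples x %d elements (%.1f%% below LOD)\n",
              ncol(object), nrow(object),
              100 * mean(assay(object, "belowLOD"))))
})

setMethod("show", "PeakList", function(object) {
  cat(sprintf("PeakList: %d peaks in [%g, %g), TIC %.4g\n",
              length(object@mz), object@lo, object@hi, sum(object@intensity)))
})

setMethod("show", "BlockCompression", function(object) {
  cat(sprintf("BlockCompression '%s': %d components (%s scaling), %.1f%% variance\n",
              object@blockName, object@k, object@scalingMode,
              100 * sum(object@varExplained)))
})

setMethod("show", "FusedMatrix", function(object) {
  tab <- table(object@provenance$block)
  cat(sprintf("FusedMatrix (%s-level): %d samples x %d features [%s]\n",
              object@level, nrow(object@fused), ncol(object@fused),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
})

setMethod("show", "LatentModel", function(object) {
  cat(sprintf("LatentModel %s: a = %d%s; R2X = %s, R2Y = %s, Q2 = %s\n",
              object@kind, ncol(object@scores),
              if (ncol(object@orthoScores) > 0)
                sprintf(" (+%d orthogonal)", ncol(object@orthoScores)) else "",
              fmtNA(object@R2X), fmtNA(object@R2Y), fmtNA(object@Q2)))
})

setMethod("show", "CVResult", function(object) {
  cat(sprintf("CVResult: overall correct-classification rate %.2f%%\n",
              object@overallRate))
  print(object@confusion)
})

fmtNA <- function(x) if (is.na(x)) "NA" else sprintf("%.3f", x)
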