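# ---- REIMS spectral chain -------------------------------------------------

#' Lockmass correction of a peak list
#'
#' Single-point multiplicative recalibration: every m/z is multiplied by
#' `reference / observedLock`, the standard TOF drift model. Intensities are
#' unchanged. The default reference is the leucine-enkephalin
#' \eqn{[M-H]^-} lockmass at 554.2615 Da.
#'
#' @param peaks a [PeakList-class].
#' @param observedLock observed m/z of the lockmass compound (> 0).
#' @param reference true lockmass m/z in Da.
#' @return corrected PeakList.
#' @export
lockmassCorrect <- function(peaks, observedLock, reference = 554.2615) {
  if (missing(observedLock) || length(observedLock) != 1L ||
      !is.finite(observedLock) || observedLock <= 0)
    stop("calibration error: observed lockmass must be a single positive m/z")
  PeakList(peaks@mz * (reference / observedLock), peaks@intensity,
           peaks@lo, peaks@hi)
}

#' Background subtraction between two peak lists
#'
#' For each sample peak, background peaks within `tolerance` Da are matched
#' and their total intensity subtracted, clipping at zero. Background peaks
#' matching no sample peak are ignored.
#'
#' @param peaks,background [PeakList-class] objects with matching
#'   acquisition ranges.
#' @param tolerance m/z matching tolerance in Da.
#' @return background-subtracted PeakList.
#' @export
backgroundSubtract <- function(peaks, background, tolerance = 0.01) {
  if (peaks@lo != background@lo || peaks@hi != background@hi)
    stop("acquisition ranges differ between sample and background")
  if (length(background@mz) == 0L) return(peaks)
  ints <- peaks@intensity
  for (i in seq_along(peaks@mz)) {
    hit <- abs(background@mz - peaks@mz[i]) <= tolerance
    if (any(hit)) ints[i] <- max(0, ints[i] - sum(background@intensity[hit]))
  }
  PeakList(peaks@mz, ints, peaks@lo, peaks@hi)
}

#' Remove peaks below a fraction of the total ion count
#'
#' Peaks with intensity `< fraction * TIC` are removed; the TIC is computed
#' on the input list.
#'
#' @param peaks a [PeakList-class].
#' @param fraction relative threshold in `[0, 1)` (default 1e-5).
#' @return filtered PeakList.
#' @export
ticThresholdFilter <- function(peaks, fraction = 1e-5) {
  stopifnot(fraction >= 0, fraction < 1)
  keep <- peaks@intensity >= fraction * sum(peaks@intensity)
  PeakList(peaks@mz[keep], peaks@intensity[keep], peaks@lo, peaks@hi)
}

#' Bin a peak list onto a uniform m/z axis
#'
#' Half-open bins `[edge, edge + width)` with the left edge at `lo`;
#' intensities within a bin are summed and the bin label is the centre
#' rounded to one decimal (so a peak at 327.2324 lands in bin 327.3).
#' Peaks outside `[lo, hi)` are dropped and counted in the `"dropped"`
#' attribute.
#'
#' @param peaks a [PeakList-class].
#' @param lo,hi,width binning parameters (Da); `width` must divide
#'   `hi - lo` to machine precision. Defaults give 5500 bins.
#' @return named numeric vector of binned intensities (names are bin
#'   labels), with attributes `labels` and `dropped`.
#' @export
binSpectrum <- function(peaks, lo = 100, hi = 1200, width = 0.2) {
  nb <- (hi - lo) / width
  if (abs(nb - round(nb)) > 1e-9)
    stop("width must divide (hi - lo) exactly")
  nb <- as.integer(round(nb))
  inRange <- peaks@mz >= lo & peaks@mz < hi
  idx <- floor((peaks@mz[inRange] - lo) / width) + 1L
  v <- numeric(nb)
  if (length(idx))
    v <- as.numeric(tapplySum(peaks@intensity[inRange], idx, nb))
  labs <- binLabelsFor(lo, hi, width)
  names(v) <- format(labs, trim = TRUE)
  attr(v, "labels") <- labs
  attr(v, "dropped") <- sum(!inRange)
  v
}

tapplySum <- function(x, idx, n) {
  out <- numeric(n)
  s <- tapply(x, idx, sum)
  out[as.integer(names(s))] <- s
  out
}

#' Bin several peak lists into a SpectraBlock
#'
#' @param peakLists named list of [PeakList-class] objects (names become
#'   sample IDs).
#' @param lo,hi,width see [binSpectrum()].
#' @param class optional class label per sample.
#' @return a [SpectraBlock-class].
#' @export
binPeakLists <- function(peakLists, lo = 100, hi = 1200, width = 0.2,
                         class = NULL) {
  mats <- t(vapply(peakLists, function(p)
    as.numeric(binSpectrum(p, lo, hi, width)),
    numeric(as.integer(round((hi - lo) / width)))))
  rownames(mats) <- names(peakLists)
  SpectraBlock(mats, lo, hi, width, class = class)
}

#' Total-ion-count normalisation of a SpectraBlock
#'
#' Divides every sample (row of the samples-by-bins matrix) by its summed
#' intensity so rows sum to one; this removes the per-burn signal-yield
#' variation inherent to ambient ionisation.
#'
#' @param block a [SpectraBlock-class].
#' @return TIC-normalised SpectraBlock.
#' @export
ticNormalize <- function(block) {
  a <- assay(block, "intensity")
  tic <- colSums(a)
  zero <- tic <= 0
  if (any(zero))
    stop("normalization error: all-zero spectrum for sample(s) ",
         paste(colnames(a)[zero], collapse = ", "))
  assay(block, "intensity") <- sweep(a, 2, tic, "/")
  block
}

# ---- column scaling -------------------------------------------------------

#' Fit a per-column min-max scaler
#'
#' Stores per-column extrema so the identical transform can be applied to
#' held-out data (whose values may then fall outside `[0, 1]`; no clipping
#' is done). Constant columns map to 0.
#'
#' @param x numeric matrix.
#' @return an object of class `"minmaxFit"`.
#' @export
fitMinMax <- function(x) {
  x <- as.matrix(x)
  structure(list(min = apply(x, 2, min), max = apply(x, 2, max)),
            class = "minmaxFit")
}

#' Apply a fitted min-max scaler
#'
#' @param fit a `"minmaxFit"` from [fitMinMax()].
#' @param x numeric matrix with the same columns as the training matrix.
#' @return scaled matrix `(x - min) / (max - min)`.
#' @export
applyMinMax <- function(fit, x) {
  x <- as.matrix(x)
  if (ncol(x) != length(fit$min)) stop("column count differs from fit")
  rng <- fit$max - fit$min
  rng[rng == 0] <- 1  # constant columns map to 0
  sweep(sweep(x, 2, fit$min, "-"), 2, rng, "/")
}

#' Min-max scale a matrix column-wise
#'
#' Convenience wrapper fitting and applying [fitMinMax()]; the fit is
#' attached as the `"fit"` attribute for later reuse on held-out data.
#'
#' @param x numeric matrix.
#' @return scaled matrix with attribute `"fit"`.
#' @export
minmaxScale <- function(x) {
  fit <- fitMinMax(x)
  out <- applyMinMax(fit, x)
  attr(out, "fit") <- fit
  out
}

# ---- ICP-MS chain ---------------------------------------------------------

#' Internal-standard ratio normalisation
#'
#' Divides every sample's element signals by that sample's internal-standard
#' signal (e.g. continuously infused Rh), cancelling per-sample sensitivity
#' drift that affects analyte and internal-standard channels alike.
#'
#' @param signals numeric samples-by-elements matrix.
#' @param isSignal positive internal-standard signal per sample.
#' @return ratio matrix.
#' @export
internalStandardNormalize <- function(signals, isSignal) {
  signals <- as.matrix(signals)
  if (length(isSignal) != nrow(signals))
    stop("one internal-standard value per sample is required")
  bad <- !is.finite(isSignal) | isSignal <= 0
  if (any(bad))
    stop("data-quality error: non-positive internal standard for sample(s) ",
         paste(if (is.null(rownames(signals))) which(bad)
               else rownames(signals)[bad], collapse = ", "))
  sweep(signals, 1, isSignal, "/")
}

#' Certified-reference-material recovery check
#'
#' Computes per-element mean recovery (% of the certified value) and RSD
#' over repeated control measurements, flagging elements outside the
#' recovery bounds.
#'
#' @param controls numeric matrix of repeated CRM measurements
#'   (measurements x elements), at least two rows.
#' @param certified named certified value per element (> 0).
#' @param bounds recovery pass band in percent (default 80--120).
#' @return data.frame `element`, `meanRecovery`, `rsd`, `pass`.
#' @export
crmCheck <- function(controls, certified, bounds = c(80, 120)) {
  controls <- as.matrix(controls)
  if (nrow(controls) < 2L) stop("at least two control measurements required")
  if (ncol(controls) != length(certified))
    stop("one certified value per element is required")
  if (any(certified == 0)) stop("configuration error: zero certified value")
  rec <- sweep(controls, 2, certified, "/") * 100
  mr <- colMeans(rec)
  rsd <- 100 * apply(controls, 2, sd) / colMeans(controls)
  data.frame(element = if (is.null(colnames(controls)))
               paste0("E", seq_along(mr)) else colnames(controls),
             meanRecovery = mr, rsd = rsd,
             pass = mr >= bounds[1] & mr <= bounds[2],
             row.names = NULL)
}

#' Filter an element panel
#'
#' Drops elements whose below-LOD fraction exceeds `maxBelowLodFraction`
#' and any explicitly excluded elements (the "excessively high
#' concentration" screen is supplied as a configuration list).
#'
#' @param block an [ElementBlock-class].
#' @param maxBelowLodFraction drop elements with a larger below-LOD
#'   fraction (default 0.5).
#' @param exclude character vector of element names to drop outright.
#' @return reduced ElementBlock; surviving names via [elementNames()].
#' @export
filterElements <- function(block, maxBelowLodFraction = 0.5,
                           exclude = character()) {
  frac <- rowMeans(assay(block, "belowLOD"))
  keep <- frac <= maxBelowLodFraction & !(rownames(block) %in% exclude)
  if (!any(keep)) stop("empty-panel error: all elements removed")
  block[keep, ]
}
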