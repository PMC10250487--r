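#' Fusion + classification pipeline as a classifier adapter
#'
#' Wraps data fusion and a base classifier into one
#' [classifierAdapter()] over a named list of blocks, so [kfoldCV()]
#' re-fits the fusion (compression, scaling) inside every training fold
#' and no information leaks from held-out rows.
#'
#' @param classifier a base [classifierAdapter()] operating on the fused
#'   matrix (default PLS-DA with 25 components).
#' @param level "mid" or "low".
#' @param threshold cumulative-variance threshold for mid-level
#'   compression.
#' @param scaling per-block scaling modes for mid-level fusion, recycled
#'   over blocks (default Pareto for the spectral block, unit variance for
#'   the element block).
#' @param maxComponents per-block component cap.
#' @return a [classifierAdapter()] whose `fit` takes a named block list;
#'   the fitted object carries `$fused` (the [FusedMatrix-class]) and
#'   `$model` (the fitted base classifier).
#' @export
fusionClassifier <- function(classifier = plsdaClassifier(25),
                             level = c("mid", "low"), threshold = 0.85,
                             scaling = c("pareto", "uv"),
                             maxComponents = 250) {
  level <- match.arg(level)
  classifierAdapter(
    paste0(level, "-fusion+", classifier$name),
    fit = function(blocks, y) {
      fused <- if (level == "mid")
        midLevelFuse(blocks, threshold = threshold, scaling = scaling,
                     maxComponents = maxComponents)
      else lowLevelFuse(blocks)
      model <- classifier$fit(fusedMatrix(fused), y)
      list(fused = fused, model = model, classifier = classifier)
    },
    predict = function(fit, blocks)
      fit$classifier$predict(fit$model, projectSamples(fit$fused, blocks)),
    hyper = c(list(level = level, threshold = threshold), classifier$hyper))
}

#' Outlier flagger for fusion-pipeline cross-validation
#'
#' Returns a `function(fit, blocks)` usable as the `outlierFlagger` of
#' [kfoldCV()] with a [fusionClassifier()] whose base model is a latent
#' model (PLS-DA/OPLS-DA): held-out rows are projected through the fitted
#' fusion and screened with [flagOutliers()].
#'
#' @param alpha overall flag level.
#' @return function of (fit, blocks).
#' @export
pipelineOutlierFlagger <- function(alpha = 0.05) {
  function(fit, blocks) {
    if (!is(fit$model, "LatentModel")) return(rep(FALSE, nrow(blocks[[1]])))
    flagOutliers(fit$model, projectSamples(fit$fused, blocks), alpha = alpha)
  }
}

#' Run the full two-block authentication pipeline
#'
#' Preprocesses both blocks (TIC normalisation of the spectra), fuses them
#' at the requested level, cross-validates the classifier with per-fold
#' transform re-fitting, fits the full-data pipeline for reporting (fused
#' width, per-block component counts, R2X/R2Y and optionally Q2), and, on
#' request, computes one-vs-rest S-plot biomarkers on the spectral block.
#'
#' @param spectra a [SpectraBlock-class].
#' @param elements an [ElementBlock-class].
#' @param labels class labels (defaults to the spectra block's classes).
#' @param classifier base [classifierAdapter()].
#' @param level,threshold,scaling see [fusionClassifier()].
#' @param folds CV folds (default 5).
#' @param seed RNG seed.
#' @param markers also compute the S-plot marker selection (slower).
#' @param q2 also compute the fused PLS-DA Q2 by 7-fold CV.
#' @return list with `cv` ([CVResult-class]), `fused`, `model`, `metrics`
#'   (named list) and optionally `markers`.
#' @export
runPipeline <- function(spectra, elements, labels = classLabels(spectra),
                        classifier = plsdaClassifier(25),
                        level = "mid", threshold = 0.85,
                        scaling = c("pareto", "uv"), folds = 5, seed = 1,
                        markers = FALSE, q2 = FALSE) {
  if (is.null(labels)) stop("config error: class labels are required")
  labels <- factor(labels)
  spectra <- ticNormalize(spectra)
  blocks <- list(reims = intensities(spectra), icpms = intensities(elements))
  adapter <- fusionClassifier(classifier, level = level,
                              threshold = threshold, scaling = scaling)
  cv <- kfoldCV(adapter, blocks, labels, folds = folds, seed = seed)
  set.seed(seed)
  fit <- adapter$fit(blocks, labels)
  km <- vapply(fit$fused@transforms, function(tr)
    if (is(tr, "BlockCompression")) tr@k else NA_integer_, integer(1))
  metrics <- list(
    classifier = adapter$name,
    overallRate = overallRate(cv),
    perClassRate = as.list(perClassRate(cv)),
    fusedWidth = ncol(fusedMatrix(fit$fused)),
    blockComponents = as.list(km),
    seed = seed, folds = folds)
  if (is(fit$model, "LatentModel")) {
    metrics$R2X <- fit$model@R2X
    metrics$R2Y <- fit$model@R2Y
    if (q2)
      metrics$Q2 <- plsQ2(fusedMatrix(fit$fused), labels,
                          a = ncol(fit$model@scores), folds = 7, seed = seed)
  }
  out <- list(cv = cv, fused = fit$fused, model = fit$model,
              metrics = metrics)
  if (markers) {
    Xs <- intensities(spectra)
    sp <- oneVsRestSPlots(Xs, labels, aOrtho = 1, scaling = "pareto")
    out$markers <- list(splots = sp, selection = selectBiomarkers(sp))
  }
  out
}
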