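# stratified fold assignment: every class spread over all folds
stratifiedFolds <- function(y, folds, seed) {
  set.seed(seed)
  id <- integer(length(y))
  for (g in levels(y)) {
    idx <- which(y == g)
    id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  id
}

subsetRows <- function(X, idx) {
  if (is.list(X) && !is.data.frame(X))
    lapply(X, function(b) b[idx, , drop = FALSE])
  else X[idx, , drop = FALSE]
}

#' Stratified k-fold cross-validated classification
#'
#' Each fold is predicted by a model fitted on the remaining folds; the
#' adapter's `fit` is called inside the loop, so any fusion, compression or
#' scaling the adapter performs is re-fitted per training fold and no
#' information leaks from the held-out rows. `X` may be a plain matrix or a
#' named list of aligned block matrices (for pipeline adapters such as
#' [fusionClassifier()]).
#'
#' @param adapter a [classifierAdapter()].
#' @param X samples-by-variables matrix, or list of such blocks.
#' @param labels class labels (each class needs at least `folds` members).
#' @param folds number of folds (default 5).
#' @param stratified stratify the partition by class (default TRUE).
#' @param seed RNG seed for the partition (and for any stochastic fit).
#' @param outlierFlagger optional `function(model, Xtest) -> logical`;
#'   flagged predictions land in the confusion's Outlier column and count
#'   as incorrect.
#' @return a [CVResult-class].
#' @export
kfoldCV <- function(adapter, X, labels, folds = 5, stratified = TRUE,
                    seed = 1, outlierFlagger = NULL) {
  labels <- factor(labels)
  n <- length(labels)
  if (folds < 2) stop("configuration error: folds must be >= 2")
  if (stratified && any(table(labels) < folds))
    stop("stratification error: every class needs at least ", folds,
         " members")
  foldId <- if (stratified) stratifiedFolds(labels, folds, seed)
            else { set.seed(seed); sample(rep_len(seq_len(folds), n)) }
  lv <- levels(labels)
  conf <- matrix(0L, length(lv), length(lv) + 1L,
                 dimnames = list(lv, c(lv, "Outlier")))
  allPred <- character(n)
  for (f in seq_len(folds)) {
    te <- foldId == f
    set.seed(seed + f)   # deterministic stochastic fits (e.g. RF)
    model <- adapter$fit(subsetRows(X, !te), labels[!te])
    pred <- as.character(adapter$predict(model, subsetRows(X, te)))
    if (!is.null(outlierFlagger)) {
      out <- outlierFlagger(model, subsetRows(X, te))
      pred[out] <- "Outlier"
    }
    tab <- unclass(table(factor(as.character(labels[te]), levels = lv),
                         factor(pred, levels = c(lv, "Outlier"))))
    conf <- conf + tab
    allPred[te] <- pred
  }
  perClass <- 100 * diag(conf[, lv, drop = FALSE]) / rowSums(conf)
  overall <- 100 * sum(diag(conf[, lv, drop = FALSE])) / sum(conf)
  new("CVResult", confusion = conf, perClassRate = perClass,
      overallRate = overall, foldAssign = as.integer(foldId),
      predictions = allPred, seed = as.integer(seed))
}

#' Flag outlying samples against a latent model
#'
#' A row is flagged when its Hotelling \eqn{T^2} over the model scores
#' exceeds the F-based control limit, or its residual distance to the model
#' plane exceeds the limit estimated from the training residuals. The two
#' limits are each taken at `1 - alpha/2` (a Bonferroni split), so the
#' family-wise training flag rate calibrates to `alpha`.
#'
#' @param model a fitted [LatentModel-class].
#' @param X rows to screen (training variable axis).
#' @param alpha overall flag level (default 0.05).
#' @return logical outlier mask.
#' @export
flagOutliers <- function(model, X, alpha = 0.05) {
  pr <- latentProject(model, X)
  a <- ncol(model@scores); n <- nrow(model@scores)
  lambda <- colSums(model@scores^2) / (n - 1)
  t2 <- rowSums(sweep(pr$scores^2, 2, lambda, "/"))
  t2lim <- a * (n - 1) * (n + 1) / (n * (n - a)) *
    stats::qf(1 - alpha / 2, a, n - a)
  resLim <- quantile(model@trainResid, 1 - alpha / 2, type = 1)
  t2 > t2lim | pr$residual > resLim
}

#' Evaluate replicated held-out test samples through a fitted pipeline
#'
#' Each replicate row is predicted (and optionally outlier-screened); the
#' sample-level call is the majority vote over non-outlier replicates (all
#' replicates flagged gives the call "Outlier"). Accuracy is reported
#' against the declared labels.
#'
#' @param predictFun `function(X or blocks) -> factor` mapping replicate
#'   rows to labels (e.g. the predictor of a fitted [fusionClassifier()]).
#' @param testX matrix or named block list of replicate rows.
#' @param sampleOf integer sample index per replicate row (constant
#'   replicate count per sample).
#' @param declared declared label per sample.
#' @param outlierFun optional `function(X or blocks) -> logical` replicate
#'   outlier mask.
#' @return list of class `"TestReport"`: `replicatePred`, `call`,
#'   `outliers`, `accuracy` (%), `nOutlierReplicates`.
#' @export
evaluateTestSamples <- function(predictFun, testX, sampleOf, declared,
                                outlierFun = NULL) {
  sampleOf <- as.integer(sampleOf)
  if (length(unique(table(sampleOf))) != 1L)
    stop("input error: replicate count differs between samples")
  pred <- as.character(predictFun(testX))
  out <- if (is.null(outlierFun)) rep(FALSE, length(pred))
         else outlierFun(testX)
  ns <- max(sampleOf)
  call <- character(ns)
  for (s in seq_len(ns)) {
    idx <- sampleOf == s
    ok <- idx & !out
    call[s] <- if (!any(ok)) "Outlier" else {
      tab <- table(pred[ok])
      names(tab)[which.max(tab)]
    }
  }
  declared <- as.character(declared)
  structure(list(replicatePred = pred, replicateOutlier = out, call = call,
                 declared = declared,
                 accuracy = 100 * mean(call == declared),
                 nOutlierReplicates = sum(out)),
            class = "TestReport")
}

#' @export
print.TestReport <- function(x, ...) {
  cat(sprintf("TestReport: %d samples, %.1f%% correct, %d outlier replicates\n",
              length(x$call), x$accuracy, x$nOutlierReplicates))
  invisible(x)
}

# ---- univariate element statistics ---------------------------------------

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square tail on `g - 1` degrees
#' of freedom (delegates to [stats::kruskal.test()], whose statistic is the
#' tie-corrected rank formula). All-identical data give H = 0, p = 1.
#'
#' @param groups list of numeric vectors, one per group.
#' @return list with `H`, `p`, `df`.
#' @export
kruskalWallis <- function(groups) {
  stopifnot(length(groups) >= 2L, all(lengths(groups) >= 1L))
  if (length(unique(unlist(groups))) == 1L)
    return(list(H = 0, p = 1, df = length(groups) - 1L))
  k <- kruskal.test(groups)
  list(H = unname(k$statistic), p = k$p.value, df = unname(k$parameter))
}

#' Pairwise two-sided Mann-Whitney comparisons with multiplicity correction
#'
#' @param groups named list of numeric vectors.
#' @param correction a [stats::p.adjust()] method (default "holm").
#' @return symmetric matrix of corrected p-values, diagonal 1.
#' @export
pairwiseCompare <- function(groups, correction = "holm") {
  g <- length(groups)
  stopifnot(g >= 2L)
  nms <- if (is.null(names(groups))) paste0("G", seq_len(g)) else names(groups)
  pm <- matrix(1, g, g, dimnames = list(nms, nms))
  pairs <- utils::combn(g, 2)
  raw <- apply(pairs, 2, function(ij)
    suppressWarnings(wilcox.test(groups[[ij[1]]],
                                 groups[[ij[2]]])$p.value))
  adj <- p.adjust(raw, method = correction)
  for (j in seq_len(ncol(pairs)))
    pm[pairs[1, j], pairs[2, j]] <- pm[pairs[2, j], pairs[1, j]] <- adj[j]
  pm
}

#' Min-max-scaled group-mean heatmap matrix
#'
#' Per-element group means, min-max scaled per element across groups (the
#' element with its highest mean in exactly one group gets 1 there;
#' constant elements map to 0).
#'
#' @param block an [ElementBlock-class].
#' @param labels group label per sample (defaults to the block's classes).
#' @return groups x elements matrix with values in `[0, 1]`.
#' @export
heatmapMatrix <- function(block, labels = classLabels(block)) {
  if (is.null(labels)) stop("group labels are required")
  labels <- factor(labels)
  x <- intensities(block)
  gm <- apply(x, 2, function(v) tapply(v, labels, mean))  # groups x elements
  sc <- apply(gm, 2, function(v) {
    r <- max(v) - min(v)
    if (r == 0) rep(0, length(v)) else (v - min(v)) / r
  })
  dimnames(sc) <- list(levels(labels), colnames(x))
  sc
}

#' Approximate CV-ANOVA for a cross-validated PLS-DA model
#'
#' A documented approximation to the SIMCA-style CV-ANOVA: an F statistic
#' comparing the cross-validated predictive residual sum of squares (PRESS)
#' against the total Y variation, with `a` model and `n - a - 1` error
#' degrees of freedom. A label-permutation test (recommended significance
#' measure) is returned alongside: its p-value has resolution
#' `1/(nPerm + 1)`, so the minimum reportable p with 999 permutations is
#' 0.001.
#'
#' @param X samples-by-variables matrix.
#' @param y class labels.
#' @param a PLS components.
#' @param folds CV folds (default 7).
#' @param seed RNG seed.
#' @param nPerm label permutations for the permutation alternative
#'   (default 999; 0 skips it).
#' @return list with `F`, `p` (approximation), `Q2`, `permP` (NA when
#'   skipped).
#' @export
cvAnova <- function(X, y, a = 2, folds = 7, seed = 1, nPerm = 999) {
  X <- as.matrix(X); y <- factor(y)
  n <- nrow(X)
  q2 <- plsQ2(X, y, a, folds = folds, seed = seed)
  Y <- oneHot(y)
  ssY <- sum(sweep(Y, 2, colMeans(Y), "-")^2)
  press <- (1 - q2) * ssY
  df1 <- a; df2 <- max(1L, n - a - 1L)
  Fstat <- max(0, (ssY - press) / df1) / (press / df2)
  p <- pf(Fstat, df1, df2, lower.tail = FALSE)
  permP <- NA_real_
  if (nPerm > 0) {
    set.seed(seed)
    exceed <- 0L
    for (b in seq_len(nPerm)) {
      q2p <- plsQ2(X, sample(y), a, folds = folds, seed = seed + b)
      if (q2p >= q2) exceed <- exceed + 1L
    }
    permP <- (1 + exceed) / (nPerm + 1)
  }
  list(F = Fstat, p = p, Q2 = q2, permP = permP)
}
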