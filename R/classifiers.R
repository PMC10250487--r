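# ---- k-NN (implemented directly: the vote/tie rules are part of the
# ---- contract and not offered by stock implementations) -------------------

#' k-nearest-neighbour prediction
#'
#' Majority vote among the `k` nearest training samples by the chosen
#' metric. Vote ties are broken by the smallest mean distance to the query,
#' then by lowest class index; distance ties are broken by training order.
#'
#' @param trainX,trainY training matrix and labels.
#' @param queryX query matrix (same variable axis).
#' @param k neighbourhood size (default 5, the optimised salmon setting).
#' @param metric "euclidean" or "manhattan".
#' @return factor of predicted labels.
#' @export
knnPredict <- function(trainX, trainY, queryX, k = 5,
                       metric = c("euclidean", "manhattan")) {
  metric <- match.arg(metric)
  trainX <- as.matrix(trainX); queryX <- as.matrix(queryX)
  if (nrow(trainX) == 0L) stop("empty training set")
  if (k > nrow(trainX)) stop("k exceeds the number of training samples")
  trainY <- factor(trainY)
  lv <- levels(trainY)
  pred <- character(nrow(queryX))
  for (i in seq_len(nrow(queryX))) {
    d <- if (metric == "euclidean")
      sqrt(rowSums(sweep(trainX, 2, queryX[i, ], "-")^2))
    else rowSums(abs(sweep(trainX, 2, queryX[i, ], "-")))
    nn <- order(d)[seq_len(k)]         # order() breaks distance ties by index
    votes <- table(trainY[nn])
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1L) {
      meand <- vapply(top, function(g) mean(d[nn][trainY[nn] == g]),
                      numeric(1))
      top <- top[meand == min(meand)]
      top <- top[order(match(top, lv))]  # residual tie: lowest class index
    }
    pred[i] <- top[1]
  }
  factor(pred, levels = lv)
}

# ---- LDA / PCA-LDA --------------------------------------------------------

#' Linear discriminant analysis (fit / predict)
#'
#' Thin wrapper around [MASS::lda()] with proportional priors; a singular
#' pooled within-class covariance raises an error advising [pcaLda()]
#' (which guarantees invertibility by first compressing to a few principal
#' components).
#'
#' @param X samples-by-variables matrix.
#' @param y class labels.
#' @return fitted object of class `"fusLDA"`.
#' @export
ldaFit <- function(X, y) {
  X <- as.matrix(X); y <- factor(y)
  wss <- X
  for (g in levels(y)) {
    idx <- y == g
    wss[idx, ] <- sweep(X[idx, , drop = FALSE], 2,
                        colMeans(X[idx, , drop = FALSE]), "-")
  }
  if (qr(wss)$rank < ncol(X))
    stop("singularity error: pooled within-class covariance is singular; ",
         "use pcaLda()")
  fit <- MASS::lda(x = X, grouping = y)
  structure(list(lda = fit, classes = levels(y)), class = "fusLDA")
}

#' @rdname ldaFit
#' @param model a fitted `"fusLDA"` object.
#' @export
ldaPredict <- function(model, X) {
  p <- predict(model$lda, as.matrix(X))$class
  factor(as.character(p), levels = model$classes)
}

#' PCA-LDA: linear discriminants in a PCA-compressed space
#'
#' Chains a fitted PCA compression (first `nPcs` components) before LDA and
#' stores both, so prediction projects new samples through the stored
#' compression. The compression makes the pooled covariance full-rank even
#' for wide spectral matrices.
#'
#' @inheritParams ldaFit
#' @param nPcs number of principal components retained before LDA.
#' @param scaling scaling before PCA (default "none").
#' @return fitted object of class `"fusPCALDA"`.
#' @export
pcaLda <- function(X, y, nPcs = 10, scaling = "none") {
  X <- as.matrix(X); y <- factor(y)
  nPcs <- min(nPcs, nrow(X) - 1L, ncol(X))
  cb <- compressBlock(X, threshold = 1, scaling = scaling, k = nPcs,
                      blockName = "pca")
  lda <- ldaFit(cb$scores, y)
  structure(list(compression = cb$compression, lda = lda,
                 classes = levels(y)), class = "fusPCALDA")
}

#' @rdname pcaLda
#' @param model a fitted `"fusPCALDA"` object.
#' @export
pcaLdaPredict <- function(model, X) {
  ldaPredict(model$lda, compressionScores(model$compression, as.matrix(X)))
}

# ---- generic classifier adapter ------------------------------------------

#' Build a classifier adapter
#'
#' An adapter is a uniform fit/predict contract used by [kfoldCV()] and the
#' pipeline: `fit(X, y)` returns a fitted model, `predict(model, X)` a
#' factor of labels. Adapters never mutate their inputs and are
#' deterministic under a fixed seed.
#'
#' @param name adapter name.
#' @param fit function(X, y) -> model.
#' @param predict function(model, X) -> factor.
#' @param hyper named list of hyperparameters (stored for reporting).
#' @return object of class `"ClassifierAdapter"`.
#' @export
classifierAdapter <- function(name, fit, predict, hyper = list()) {
  structure(list(name = name, fit = fit, predict = predict, hyper = hyper),
            class = "ClassifierAdapter")
}

#' @export
print.ClassifierAdapter <- function(x, ...) {
  h <- if (length(x$hyper))
    paste0(" (", paste(names(x$hyper), unlist(x$hyper), sep = "=",
                       collapse = ", "), ")") else ""
  cat("ClassifierAdapter:", x$name, h, "\n")
  invisible(x)
}

#' Stock classifier adapters
#'
#' Ready-made [classifierAdapter()]s for the classifier comparison:
#' k-NN (`k = 5`), PLS-DA (`a = 25`), OPLS-DA, LDA, PCA-LDA, random forest
#' (`ntree = 500`, `mtry = 15`; requires \pkg{randomForest}) and RBF SVM
#' (default kernel settings; requires \pkg{e1071}). RF and SVM internals
#' are deliberately not re-implemented; the adapters plug the external
#' implementations into the comparison.
#'
#' @param k,a,aOrtho,nPcs,ntree,mtry,... hyperparameters passed through.
#' @name adapters
NULL

#' @rdname adapters
#' @export
knnClassifier <- function(k = 5) {
  classifierAdapter("kNN",
    fit = function(X, y) list(X = as.matrix(X), y = factor(y), k = k),
    predict = function(model, X) knnPredict(model$X, model$y, X, model$k),
    hyper = list(k = k))
}

#' @rdname adapters
#' @export
plsdaClassifier <- function(a = 25) {
  classifierAdapter("PLS-DA",
    fit = function(X, y) plsdaFit(X, y, a = a),
    predict = plsdaPredict, hyper = list(components = a))
}

#' @rdname adapters
#' @export
oplsdaClassifier <- function(aOrtho = 1, a = NULL) {
  classifierAdapter("OPLS-DA",
    fit = function(X, y) oplsdaFit(X, y, aOrtho = aOrtho, aPred = a),
    predict = oplsdaPredict, hyper = list(aOrtho = aOrtho))
}

#' @rdname adapters
#' @export
ldaClassifier <- function() {
  classifierAdapter("LDA", fit = ldaFit, predict = ldaPredict)
}

#' @rdname adapters
#' @export
pcaLdaClassifier <- function(nPcs = 10) {
  classifierAdapter("PCA-LDA",
    fit = function(X, y) pcaLda(X, y, nPcs = nPcs),
    predict = pcaLdaPredict, hyper = list(nPcs = nPcs))
}

#' @rdname adapters
#' @export
rfClassifier <- function(ntree = 500, mtry = 15, ...) {
  if (!requireNamespace("randomForest", quietly = TRUE))
    stop("package 'randomForest' is required for the RF adapter")
  classifierAdapter("RF",
    fit = function(X, y)
      randomForest::randomForest(as.matrix(X), factor(y), ntree = ntree,
                                 mtry = min(mtry, ncol(X)), ...),
    predict = function(model, X)
      factor(as.character(predict(model, as.matrix(X))),
             levels = model$classes),
    hyper = list(ntree = ntree, npredic = mtry))
}

#' @rdname adapters
#' @export
svmClassifier <- function(...) {
  if (!requireNamespace("e1071", quietly = TRUE))
    stop("package 'e1071' is required for the SVM adapter")
  classifierAdapter("SVM",
    fit = function(X, y) e1071::svm(as.matrix(X), factor(y),
                                    kernel = "radial", ...),
    predict = function(model, X)
      factor(as.character(predict(model, as.matrix(X))),
             levels = model$levels),
    hyper = list(kernel = "radial"))
}
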