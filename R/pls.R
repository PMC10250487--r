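# one-hot encoding of a factor response
oneHot <- function(y) {
  y <- factor(y)
  if (nlevels(y) < 2L)
    stop("degenerate-label error: at least two classes are required")
  Y <- matrix(0, length(y), nlevels(y),
              dimnames = list(NULL, levels(y)))
  Y[cbind(seq_along(y), as.integer(y))] <- 1
  Y
}

# NIPALS PLS2 on centered (X, Y); returns W, P, C, T and residuals
nipalsPLS2 <- function(Xc, Yc, a, tol = 1e-10, maxIter = 500) {
  n <- nrow(Xc); p <- ncol(Xc); m <- ncol(Yc)
  a <- min(a, n - 1L, p)
  W <- matrix(0, p, a); P <- matrix(0, p, a)
  C <- matrix(0, m, a); T <- matrix(0, n, a)
  E <- Xc; F <- Yc
  ssX <- sum(Xc^2)
  used <- 0L
  for (i in seq_len(a)) {
    if (sum(F^2) < 1e-12 * max(1, sum(Yc^2)) || sum(E^2) < 1e-14 * ssX) break
    u <- F[, which.max(colSums(F^2))]
    t <- u
    for (it in seq_len(maxIter)) {
      w <- crossprod(E, u); w <- w / sqrt(sum(w^2))
      tNew <- E %*% w
      cc <- crossprod(F, tNew) / sum(tNew^2)
      u <- F %*% cc / sum(cc^2)
      if (sqrt(sum((tNew - t)^2)) < tol * sqrt(sum(tNew^2))) { t <- tNew; break }
      t <- tNew
      if (it == maxIter) warning("PLS NIPALS did not converge for component ", i)
    }
    w <- crossprod(E, u); w <- w / sqrt(sum(w^2))
    t <- as.numeric(E %*% w)
    tt <- sum(t^2)
    if (tt < 1e-14 * ssX) break
    pp <- crossprod(E, t) / tt
    cc <- crossprod(F, t) / tt
    E <- E - tcrossprod(t, pp)
    F <- F - tcrossprod(t, cc)
    W[, i] <- w; P[, i] <- pp; C[, i] <- cc; T[, i] <- t
    used <- i
  }
  idx <- seq_len(used)
  list(W = W[, idx, drop = FALSE], P = P[, idx, drop = FALSE],
       C = C[, idx, drop = FALSE], T = T[, idx, drop = FALSE],
       E = E, F = F, a = used)
}

plsCoef <- function(W, P, C)
  W %*% solve(crossprod(P, W)) %*% t(C)

#' Fit a PLS-DA model
#'
#' NIPALS PLS2 regression of a one-hot class encoding on X; prediction is
#' the argmax over predicted class columns. Components whose score variance
#' vanishes are not extracted, so the effective component count can be
#' smaller than `a`.
#'
#' @param X numeric samples-by-variables matrix.
#' @param y class labels (>= 2 classes).
#' @param a requested number of components (default 25, the optimised
#'   setting for the fused salmon blocks).
#' @param center,scaling see [nipalsPCA()].
#' @param q2Folds if > 0, cumulative \eqn{Q^2 = 1 - PRESS/SS(Y)} is
#'   estimated by row-wise `q2Folds`-fold CV (0 skips it).
#' @param seed RNG seed for the Q2 fold partition.
#' @return a [LatentModel-class] of kind "PLSDA".
#' @export
plsdaFit <- function(X, y, a = 25, center = TRUE, scaling = "none",
                     q2Folds = 0, seed = 1) {
  y <- factor(y)
  Y <- oneHot(y)
  cs <- centerScale(X, center, scaling)
  yMeans <- colMeans(Y)
  Yc <- sweep(Y, 2, yMeans, "-")
  fit <- nipalsPLS2(cs$X, Yc, a)
  if (fit$a == 0L) stop("no PLS component could be extracted")
  B <- plsCoef(fit$W, fit$P, fit$C)
  ssX <- sum(cs$X^2); ssY <- sum(Yc^2)
  ve <- colSums(fit$T^2) * colSums(fit$P^2) / ssX
  q2 <- NA_real_
  if (q2Folds > 0)
    q2 <- plsQ2(X, y, a, folds = q2Folds, seed = seed, center = center,
                scaling = scaling)
  newLatent("PLSDA", cs, fit$T, fit$P, fit$W, fit$C,
            emptyMat(nrow(cs$X)), emptyMat(ncol(cs$X)), emptyMat(ncol(cs$X)),
            B, levels(y), yMeans,
            R2X = 1 - sum(fit$E^2) / ssX, R2Y = 1 - sum(fit$F^2) / ssY,
            Q2 = q2, varExplained = ve,
            trainResid = sqrt(rowSums(fit$E^2)))
}

#' Predict class labels from a PLS-DA / OPLS-DA model
#'
#' Predicted one-hot columns are computed from the stored coefficients and
#' the class is the argmax; exact ties go to the lowest class index with a
#' warning.
#'
#' @param model a [LatentModel-class] of kind "PLSDA" or "OPLSDA".
#' @param X new samples on the training variable axis.
#' @return factor of predicted labels.
#' @export
plsdaPredict <- function(model, X) {
  if (!model@kind %in% c("PLSDA", "OPLSDA"))
    stop("not a discriminant PLS model")
  Xc <- applyCenterScale(model, X)
  Xc <- oscFilter(model, Xc)
  Yhat <- sweep(Xc %*% model@coef, 2, model@yMeans, "+")
  pick <- apply(Yhat, 1, function(r) {
    w <- which(r == max(r))
    if (length(w) > 1L) warning("prediction tie broken by class order")
    w[1]
  })
  factor(model@classes[pick], levels = model@classes)
}

#' Cumulative Q2 of a PLS-DA model by cross-validation
#'
#' \eqn{Q^2 = 1 - PRESS / SS(Y)} with row-wise fold exclusion; PRESS is
#' accumulated over the one-hot response predicted for each left-out fold.
#'
#' @inheritParams plsdaFit
#' @param folds number of folds (default 7).
#' @param seed RNG seed for the partition.
#' @return cumulative Q2 (can be negative for uninformative X).
#' @export
plsQ2 <- function(X, y, a = 25, folds = 7, seed = 1, center = TRUE,
                  scaling = "none") {
  X <- as.matrix(X); y <- factor(y)
  n <- nrow(X)
  if (folds < 2 || folds > n) stop("configuration error: bad fold count")
  Y <- oneHot(y)
  set.seed(seed)
  foldId <- sample(rep_len(seq_len(folds), n))
  press <- 0
  for (f in seq_len(folds)) {
    te <- foldId == f
    fit <- plsdaFit(X[!te, , drop = FALSE], y[!te], a, center, scaling)
    Xc <- applyCenterScale(fit, X[te, , drop = FALSE])
    Yhat <- sweep(Xc %*% fit@coef, 2, fit@yMeans, "+")
    press <- press + sum((Y[te, , drop = FALSE] - Yhat)^2)
  }
  ssY <- sum(sweep(Y, 2, colMeans(Y), "-")^2)
  1 - press / ssY
}

#' Variable importance in projection (VIP)
#'
#' \eqn{VIP_j = \sqrt{p \sum_a SSY_a (w_{ja}/\|w_a\|)^2 / \sum_a SSY_a}}
#' where \eqn{SSY_a} is the Y sum of squares explained by component `a`.
#' The mean of squared VIPs is exactly 1.
#'
#' @param model a fitted PLS-family [LatentModel-class].
#' @return numeric VIP score per variable.
#' @export
vip <- function(model) {
  W <- model@weights
  if (ncol(W) == 0L) stop("VIP requires a PLS-family model")
  Wn <- sweep(W, 2, sqrt(colSums(W^2)), "/")
  ssy <- colSums(model@scores^2) * colSums(as.matrix(model@yloadings)^2)
  p <- nrow(W)
  sqrt(p * as.numeric(Wn^2 %*% ssy) / sum(ssy))
}
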