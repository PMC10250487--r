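# ---- shared preprocessing -------------------------------------------------

# center/scale X; scaling: none, uv (unit variance), pareto (sqrt sd)
centerScale <- function(X, center = TRUE, scaling = c("none", "uv", "pareto")) {
  scaling <- match.arg(scaling)
  X <- as.matrix(X)
  ctr <- if (center) colMeans(X) else rep(0, ncol(X))
  s <- apply(X, 2, sd)
  scl <- switch(scaling, none = rep(1, ncol(X)), uv = s, pareto = sqrt(s))
  scl[scl == 0] <- 1   # constant columns pass through unscaled
  list(X = sweep(sweep(X, 2, ctr, "-"), 2, scl, "/"), center = ctr,
       scale = scl, scalingMode = scaling)
}

applyCenterScale <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(model@center))
    stop("variable-axis mismatch: expected ", length(model@center),
         " columns, got ", ncol(X))
  sweep(sweep(X, 2, model@center, "-"), 2, model@scale, "/")
}

emptyMat <- function(nr) matrix(0, nr, 0)

newLatent <- function(kind, cs, T, P, W, C, To, Po, Wo, B, classes, yMeans,
                      R2X, R2Y, Q2, varExplained, trainResid) {
  new("LatentModel", kind = kind, center = cs$center, scale = cs$scale,
      scalingMode = cs$scalingMode, scores = T, loadings = P, weights = W,
      yloadings = C, orthoScores = To, orthoLoadings = Po, orthoWeights = Wo,
      coef = B, classes = classes, yMeans = yMeans, R2X = R2X, R2Y = R2Y,
      Q2 = Q2, varExplained = varExplained, trainResid = trainResid)
}

# ---- NIPALS PCA -----------------------------------------------------------

#' NIPALS principal component analysis
#'
#' Iterative NIPALS extraction with deflation. Initialisation is
#' deterministic (the residual column of maximal variance), per-component
#' explained variance is \eqn{\|t_i p_i'\|_F^2 / \|X\|_F^2}, and
#' \eqn{R^2X(cum) = 1 - \|E\|_F^2 / \|X\|_F^2}.
#'
#' @param X numeric matrix (samples x variables).
#' @param a number of components (`a <= min(n - 1, p)` after centering).
#' @param center center columns (default TRUE).
#' @param scaling "none", "uv" or "pareto".
#' @param tol relative convergence tolerance on the score vector.
#' @param maxIter maximum NIPALS iterations per component (a convergence
#'   warning is raised and the component returned as-is).
#' @return a [LatentModel-class] of kind "PCA".
#' @export
nipalsPCA <- function(X, a, center = TRUE, scaling = "none",
                      tol = 1e-10, maxIter = 500) {
  cs <- centerScale(X, center, scaling)
  E <- cs$X
  n <- nrow(E); p <- ncol(E)
  a <- min(a, if (center) n - 1L else n, p)
  ssTot <- sum(E^2)
  if (ssTot == 0) stop("degenerate-input error: zero-variance matrix")
  T <- matrix(0, n, a); P <- matrix(0, p, a)
  ve <- numeric(a)
  for (i in seq_len(a)) {
    vars <- colSums(E^2)
    if (max(vars) < ssTot * 1e-14) { a <- i - 1L; break }
    t <- E[, which.max(vars)]
    for (it in seq_len(maxIter)) {
      pp <- crossprod(E, t) / sum(t^2)
      pp <- pp / sqrt(sum(pp^2))
      tNew <- E %*% pp
      if (sqrt(sum((tNew - t)^2)) < tol * sqrt(sum(tNew^2))) { t <- tNew; break }
      t <- tNew
      if (it == maxIter)
        warning("NIPALS did not converge for component ", i)
    }
    pp <- crossprod(E, t) / sum(t^2)
    pp <- pp / sqrt(sum(pp^2))
    t <- as.numeric(E %*% pp)
    T[, i] <- t; P[, i] <- pp
    E <- E - tcrossprod(t, pp)
    ve[i] <- sum(t^2) / ssTot
  }
  T <- T[, seq_len(a), drop = FALSE]; P <- P[, seq_len(a), drop = FALSE]
  ve <- ve[seq_len(a)]
  newLatent("PCA", cs, T, P, emptyMat(p), emptyMat(0),
            emptyMat(n), emptyMat(p), emptyMat(p), matrix(0, p, 0),
            character(0), numeric(0),
            R2X = sum(ve), R2Y = NA_real_, Q2 = NA_real_,
            varExplained = ve, trainResid = sqrt(rowSums(E^2)))
}

#' Project new samples into a latent model's score space
#'
#' Applies the stored centering/scaling and, for OPLS models, the
#' orthogonal-signal-correction filter, then computes predictive scores.
#' Never re-fits.
#'
#' @param model a [LatentModel-class].
#' @param X new samples on the training variable axis.
#' @return list with `scores` (n x a) and `residual` (distance to the
#'   model plane per row).
#' @export
latentProject <- function(model, X) {
  Xc <- applyCenterScale(model, X)
  Xf <- oscFilter(model, Xc)
  T <- switch(model@kind,
    PCA = Xf %*% model@loadings,
    {
      W <- model@weights; P <- model@loadings
      Xf %*% W %*% solve(crossprod(P, W))
    })
  E <- Xf - tcrossprod(T, model@loadings)
  list(scores = T, residual = sqrt(rowSums(E^2)))
}

# remove stored orthogonal components from centered data (OPLS only)
oscFilter <- function(model, Xc) {
  k <- ncol(model@orthoWeights)
  if (k == 0L) return(Xc)
  for (i in seq_len(k)) {
    to <- Xc %*% model@orthoWeights[, i]
    Xc <- Xc - tcrossprod(to, model@orthoLoadings[, i])
  }
  Xc
}

# ---- cross-validated Q2 for PCA ------------------------------------------

#' Cross-validated Q2 of a PCA model
#'
#' Row-wise fold exclusion: each fold's rows are reconstructed, component
#' by component, from a model fitted without them.
#' \eqn{Q^2(cum) = 1 - \prod_a PRESS_a / SS_{a-1}}, with \eqn{SS_{a-1}} the
#' residual sum of squares of the full-data model before component `a`.
#'
#' @inheritParams nipalsPCA
#' @param folds number of CV folds (default 7).
#' @param seed RNG seed for the fold partition.
#' @return list with `perComponent` Q2 values and `cum` cumulative Q2.
#' @export
q2CV <- function(X, a, folds = 7, seed = 1, center = TRUE, scaling = "none") {
  X <- as.matrix(X)
  n <- nrow(X)
  if (folds < 2 || folds > n) stop("configuration error: bad fold count")
  set.seed(seed)
  foldId <- sample(rep_len(seq_len(folds), n))
  full <- nipalsPCA(X, a, center, scaling)
  a <- ncol(full@scores)
  ssTot <- sum(centerScale(X, center, scaling)$X^2)
  # residual SS of the full model before component i: ssTot - explained(1..i-1)
  ssSeq <- ssTot * (1 - cumsum(c(0, full@varExplained)))
  press <- numeric(a)
  for (f in seq_len(folds)) {
    te <- foldId == f
    fit <- nipalsPCA(X[!te, , drop = FALSE], a, center, scaling)
    E <- applyCenterScale(fit, X[te, , drop = FALSE])
    for (i in seq_len(min(a, ncol(fit@scores)))) {
      t <- E %*% fit@loadings[, i]
      E <- E - tcrossprod(t, fit@loadings[, i])
      press[i] <- press[i] + sum(E^2)
    }
  }
  ratio <- press / ssSeq[seq_len(a)]
  list(perComponent = 1 - ratio, cum = 1 - prod(ratio))
}
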