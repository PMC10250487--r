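#' Fit an OPLS-DA model
#'
#' Orthogonal signal correction in the Trygg style: the Y-predictive weight
#' basis is the span of \eqn{X'Y} (for a single contrast, the normalised
#' \eqn{X'y} itself); each orthogonal component takes the part of the
#' X-loading orthogonal to that basis, \eqn{w_o \propto p - W_y(W_y'p)},
#' scores \eqn{t_o = X w_o}, and deflates \eqn{X \leftarrow X - t_o p_o'}.
#' The predictive PLS2 model is then fitted on the filtered X, so the
#' training decomposition satisfies \eqn{X = T P' + T_o P_o' + E} exactly
#' and every orthogonal score is exactly uncorrelated with every Y column.
#'
#' Multi-class responses are handled as multi-column-Y OPLS with argmax
#' prediction; the one-vs-rest mode used for S-plots is obtained by passing
#' a binary contrast as `y`.
#'
#' @param X numeric samples-by-variables matrix.
#' @param y class labels.
#' @param aOrtho number of orthogonal components to remove (may be 0, in
#'   which case the model is identical to a PLS-DA with `aPred`
#'   components).
#' @param aPred predictive components (default 1 for a binary contrast,
#'   `nclass - 1` otherwise).
#' @param center,scaling see [nipalsPCA()].
#' @return a [LatentModel-class] of kind "OPLSDA".
#' @export
oplsdaFit <- function(X, y, aOrtho = 1, aPred = NULL, center = TRUE,
                      scaling = "none") {
  y <- factor(y)
  Y <- oneHot(y)
  if (is.null(aPred)) aPred <- max(1L, nlevels(y) - 1L)
  cs <- centerScale(X, center, scaling)
  Xc <- cs$X
  yMeans <- colMeans(Y)
  Yc <- sweep(Y, 2, yMeans, "-")
  n <- nrow(Xc); p <- ncol(Xc)
  if (aOrtho > min(n - 1L, p) - 1L)
    stop("rank error: too many orthogonal components for the data rank")
  # orthonormal basis of the Y-predictive weight space span(X'Y)
  sv <- svd(crossprod(Xc, Yc))
  ky <- sum(sv$d > sv$d[1] * 1e-10)
  Wy <- sv$u[, seq_len(ky), drop = FALSE]
  w <- Wy[, 1]
  To <- matrix(0, n, aOrtho); Po <- matrix(0, p, aOrtho)
  Wo <- matrix(0, p, aOrtho)
  for (i in seq_len(aOrtho)) {
    t <- Xc %*% w
    pp <- as.numeric(crossprod(Xc, t) / sum(t^2))
    wo <- pp - Wy %*% crossprod(Wy, pp)
    nrm <- sqrt(sum(wo^2))
    if (nrm < 1e-12 * sqrt(sum(pp^2)))
      stop("rank error: no Y-orthogonal variation left at component ", i)
    wo <- wo / nrm
    to <- as.numeric(Xc %*% wo)
    po <- as.numeric(crossprod(Xc, to) / sum(to^2))
    Xc <- Xc - tcrossprod(to, po)
    To[, i] <- to; Po[, i] <- po; Wo[, i] <- wo
  }
  fit <- nipalsPLS2(Xc, Yc, aPred)
  if (fit$a == 0L) stop("no predictive component could be extracted")
  B <- plsCoef(fit$W, fit$P, fit$C)
  ssX <- sum(cs$X^2); ssY <- sum(Yc^2)
  ve <- colSums(fit$T^2) * colSums(fit$P^2) / ssX
  newLatent("OPLSDA", cs, fit$T, fit$P, fit$W, fit$C, To, Po, Wo, B,
            levels(y), yMeans,
            R2X = 1 - sum(fit$E^2) / ssX, R2Y = 1 - sum(fit$F^2) / ssY,
            Q2 = NA_real_, varExplained = ve,
            trainResid = sqrt(rowSums(fit$E^2)))
}

#' @rdname plsdaPredict
#' @export
oplsdaPredict <- function(model, X) plsdaPredict(model, X)

#' S-plot of an OPLS-DA contrast
#'
#' For the first predictive score t, computes per variable the
#' covariance \eqn{p1_j = cov(t, x_j)} and the correlation
#' \eqn{p(corr)1_j = p1_j / (sd(t) sd(x_j))}; zero-variance variables get
#' p(corr) 0. Variables in the upper-right / lower-left corners (high
#' covariance and high correlation magnitude) are marker candidates.
#'
#' @param model a fitted OPLS-DA (or PLS-DA) [LatentModel-class].
#' @param X the (preprocessed) data matrix the model was fitted on.
#' @param contrast optional description of the contrast (stored as an
#'   attribute).
#' @return data.frame `variable`, `p1`, `pcorr1` with attribute
#'   `"contrast"`.
#' @export
sPlot <- function(model, X, contrast = "") {
  X <- as.matrix(X)
  t <- model@scores[, 1]
  n <- length(t)
  tc <- t - mean(t)
  Xc <- sweep(X, 2, colMeans(X), "-")
  p1 <- as.numeric(crossprod(Xc, tc)) / (n - 1)
  sdx <- apply(X, 2, sd)
  pcorr <- ifelse(sdx > 0, p1 / (sd(t) * sdx), 0)
  out <- data.frame(variable = if (is.null(colnames(X)))
                      paste0("V", seq_len(ncol(X))) else colnames(X),
                    p1 = p1, pcorr1 = pcorr)
  attr(out, "contrast") <- contrast
  out
}

#' One-vs-rest OPLS-DA S-plots for every class
#'
#' Builds one binary OPLS-DA model per class (that class against the
#' remaining ones, with the predictive score oriented towards the class)
#' and returns the S-plot of each.
#'
#' @param X preprocessed samples-by-variables matrix.
#' @param y class labels.
#' @param aOrtho orthogonal components per contrast.
#' @param center,scaling see [nipalsPCA()].
#' @return named list of S-plot data.frames, one per class.
#' @export
oneVsRestSPlots <- function(X, y, aOrtho = 1, center = TRUE,
                            scaling = "none") {
  y <- factor(y)
  out <- lapply(levels(y), function(g) {
    contrast <- factor(ifelse(y == g, g, "rest"), levels = c("rest", g))
    m <- oplsdaFit(X, contrast, aOrtho = aOrtho, aPred = 1, center = center,
                   scaling = scaling)
    # orient the score towards the target class
    if (mean(m@scores[contrast == g, 1]) < 0) m@scores[, 1] <- -m@scores[, 1]
    sPlot(m, X, contrast = paste(g, "vs rest"))
  })
  names(out) <- levels(y)
  out
}

#' Select biomarker variables from one-vs-rest S-plots
#'
#' A variable is selected in a contrast when both \eqn{|p(corr)1|} passes
#' `corrCut` and \eqn{|p1|} falls in the top `1 - covQuantile` fraction of
#' the contrast's covariances; per-contrast selections are ranked by
#' \eqn{|p(corr)1|}. The consensus panel keeps variables selected in at
#' least `m` contrasts.
#'
#' @param splots named list of S-plot data.frames (one per class,
#'   one-vs-rest over all classes; see [oneVsRestSPlots()]).
#' @param corrCut absolute correlation threshold (default 0.7).
#' @param covQuantile quantile of `|p1|` a variable must exceed
#'   (default 0.9).
#' @param m minimum number of contrasts for the consensus panel
#'   (default 3).
#' @return list with `perClass` (named list of ranked variable vectors)
#'   and `consensus` (character vector).
#' @export
selectBiomarkers <- function(splots, corrCut = 0.7, covQuantile = 0.9,
                             m = 3) {
  perClass <- lapply(splots, function(s) {
    cut2 <- quantile(abs(s$p1), covQuantile)
    sel <- s[abs(s$pcorr1) >= corrCut & abs(s$p1) >= cut2, , drop = FALSE]
    sel$variable[order(-abs(sel$pcorr1))]
  })
  if (all(lengths(perClass) == 0L))
    warning("empty selection: no variable passes the cuts")
  tab <- table(unlist(perClass))
  list(perClass = perClass,
       consensus = names(tab)[tab >= m])
}
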