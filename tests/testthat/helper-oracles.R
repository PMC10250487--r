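# Independent oracles and small fixture builders used across the suite.

# kernel-algorithm PLS2: weights from the dominant eigenvector of
# X'YY'X (Hoskuldsson), a different computational path than NIPALS
kernelPLS2 <- function(X, Y, a) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  p <- ncol(Xc); m <- ncol(Yc)
  W <- matrix(0, p, a); P <- matrix(0, p, a); C <- matrix(0, m, a)
  T <- matrix(0, nrow(Xc), a)
  E <- Xc; F <- Yc
  for (i in seq_len(a)) {
    M <- crossprod(E, F)            # p x m
    ev <- eigen(M %*% t(M), symmetric = TRUE)
    w <- ev$vectors[, 1]
    t <- E %*% w
    tt <- sum(t^2)
    pp <- crossprod(E, t) / tt
    cc <- crossprod(F, t) / tt
    E <- E - tcrossprod(t, pp)
    F <- F - tcrossprod(t, cc)
    W[, i] <- w; P[, i] <- pp; C[, i] <- cc; T[, i] <- t
  }
  B <- W %*% solve(crossprod(P, W)) %*% t(C)
  list(B = B, T = T, W = W, P = P, C = C,
       xMeans = colMeans(X), yMeans = colMeans(Y))
}

# exhaustive nearest-neighbour majority vote implementing the same
# published vote/tie contract by a direct path
bruteKNN <- function(trainX, trainY, queryX, k) {
  trainY <- factor(trainY)
  lv <- levels(trainY)
  apply(as.matrix(queryX), 1, function(q) {
    d <- sqrt(colSums((t(trainX) - q)^2))
    nn <- order(d)[seq_len(k)]
    tab <- table(trainY[nn])
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1L) {
      md <- sapply(top, function(g) mean(d[nn][trainY[nn] == g]))
      top <- top[md == min(md)]
      top <- top[order(match(top, lv))]
    }
    top[1]
  })
}

# exhaustive permutation p-value for the (tie-free) Kruskal-Wallis
# statistic of two groups, via the closed rank-sum form
permKWp <- function(g1, g2) {
  pooled <- c(g1, g2)
  n1 <- length(g1); N <- length(pooled)
  r <- rank(pooled)
  hOf <- function(rs1) {
    rs2 <- N * (N + 1) / 2 - rs1
    12 / (N * (N + 1)) * (rs1^2 / n1 + rs2^2 / (N - n1)) - 3 * (N + 1)
  }
  obs <- hOf(sum(r[seq_len(n1)]))
  idx <- utils::combn(N, n1)
  hs <- hOf(colSums(matrix(r[idx], nrow = n1)))
  mean(hs >= obs - 1e-12)
}

# exhaustive permutation p-value for the two-sided rank-sum test
permMWp <- function(g1, g2) {
  pooled <- c(g1, g2)
  n1 <- length(g1)
  r <- rank(pooled)
  obs <- sum(r[seq_len(n1)])
  ev <- n1 * (length(pooled) + 1) / 2
  idx <- utils::combn(length(pooled), n1)
  ws <- apply(idx, 2, function(i) sum(r[i]))
  mean(abs(ws - ev) >= abs(obs - ev) - 1e-12)
}

# small two-block dataset; strong = default effects, null = no effects
smallDataset <- function(nPerClass = 20, seed = 42, strong = TRUE) {
  cfg <- simConfig(nPerClass = nPerClass, seed = seed)
  eff <- defaultMarkerEffects(cfg$classes)
  if (!strong) eff[, -1] <- 1
  makeDataset(cfg, effects = eff)
}

# aligned block list for pipeline adapters
asBlocks <- function(ds) {
  list(reims = intensities(ticNormalize(ds$spectra)),
       icpms = intensities(ds$elements))
}

# random peak list within [lo, hi)
randomPeaks <- function(n, lo = 100, hi = 1200, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  PeakList(runif(n, lo, hi), rexp(n), lo, hi)
}
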