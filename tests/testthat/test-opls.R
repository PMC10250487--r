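test_that("OPLS-DA with no orthogonal component reduces to 1-component PLS-DA", {
  set.seed(31)
  X <- matrix(rnorm(24 * 6), 24, 6)
  y <- factor(rep_len(c("a", "b"), 24))
  X[, 1] <- X[, 1] + ifelse(y == "a", 1.5, -1.5)
  o <- oplsdaFit(X, y, aOrtho = 0, aPred = 1)
  p <- plsdaFit(X, y, a = 1)
  expect_equal(as.character(oplsdaPredict(o, X)),
               as.character(plsdaPredict(p, X)))
  expect_equal(abs(o@coef), abs(p@coef), tolerance = 1e-8)
})

test_that("the OSC filter removes a planted Y-orthogonal factor", {
  set.seed(32)
  n <- 40
  y <- factor(rep_len(c("a", "b"), n))
  signal <- ifelse(y == "a", 2, -2)
  X <- outer(signal, c(1, 1, 0, 0, 0)) + 0.3 * matrix(rnorm(n * 5), n, 5)
  base <- oplsdaFit(X, y, aOrtho = 0, aPred = 1)
  ortho <- rnorm(n); ortho <- residuals(lm(ortho ~ signal)) * 5
  Xa <- X + outer(ortho, c(0, 0, 1, 1, 1))
  filt <- oplsdaFit(Xa, y, aOrtho = 1, aPred = 1)
  expect_gt(abs(cor(filt@scores[, 1], base@scores[, 1])), 0.999)
})

test_that("OPLS training decomposition and Y-orthogonality are exact", {
  set.seed(33)
  X <- matrix(rnorm(30 * 8), 30, 8)
  for (y in list(factor(rep_len(c("a", "b"), 30)),
                 factor(rep_len(letters[1:5], 30)))) {
    m <- oplsdaFit(X, y, aOrtho = 2)
    Xc <- fuseMS:::applyCenterScale(m, X)
    E <- fuseMS:::oscFilter(m, Xc) - tcrossprod(m@scores, m@loadings)
    recon <- tcrossprod(m@scores, m@loadings) +
      tcrossprod(m@orthoScores, m@orthoLoadings) + E
    expect_lt(max(abs(Xc - recon)), 1e-8)
    Y <- fuseMS:::oneHot(y)
    expect_lt(max(abs(cor(m@orthoScores, Y))), 1e-8)
  }
  expect_error(oplsdaFit(X[1:4, ], factor(rep(c("a", "b"), 2)), aOrtho = 5),
               "rank error")
})

test_that("orthogonal components never decrease the training R2Y", {
  set.seed(34)
  X <- matrix(rnorm(40 * 10), 40, 10)
  y <- factor(rep_len(c("a", "b"), 40))
  X[, 1] <- X[, 1] + ifelse(y == "a", 1, -1)
  r2y <- vapply(0:3, function(k)
    oplsdaFit(X, y, aOrtho = k, aPred = 1)@R2Y, numeric(1))
  expect_true(all(diff(r2y) >= -1e-9))
})

test_that("S-plot covariance/correlation match the direct oracle", {
  set.seed(35)
  X <- matrix(rnorm(50 * 6), 50, 6)
  y <- factor(rep_len(c("a", "b"), 50))
  X[, 1] <- X[, 1] + ifelse(y == "a", 2, -2)
  m <- oplsdaFit(X, y, aOrtho = 1, aPred = 1)
  s <- sPlot(m, X)
  t <- scores(m)[, 1]
  for (j in 1:6) {
    expect_equal(s$p1[j], cov(t, X[, j]), tolerance = 1e-10)
    expect_equal(s$pcorr1[j], cor(t, X[, j]), tolerance = 1e-10)
  }
  expect_true(all(abs(s$pcorr1) <= 1 + 1e-12))
  expect_true(all(sign(s$p1) == sign(s$pcorr1) | s$p1 == 0))
  # a variable equal to the score has correlation exactly 1
  X2 <- cbind(X, t)
  s2 <- sPlot(m, X2)
  expect_equal(s2$pcorr1[7], 1, tolerance = 1e-12)
  # pure-noise variables stay inside the null band
  noise <- matrix(rnorm(50 * 20), 50, 20)
  sn <- sPlot(m, noise)
  expect_lt(mean(abs(sn$pcorr1) > 3 / sqrt(50)), 0.1)
  # zero-variance variable gets pcorr 0
  s3 <- sPlot(m, cbind(X, 5))
  expect_equal(s3$pcorr1[7], 0)
})

test_that("biomarker selection recovers planted markers and builds a consensus", {
  set.seed(36)
  cfg <- simConfig(nPerClass = 12, seed = 36, hi = 120)  # 100-bin axis
  eff <- data.frame(bin = c(101.1, 105.3, 110.5),
                    a = c(9, 1, 4), b = c(1, 9, 4), c = c(9, 9, 1),
                    d = c(1, 1, 4), e = c(9, 1, 1))
  cfg$classes <- letters[1:5]
  sb <- sampleSpectraBlock(cfg, effects = eff, seed = 36)
  X <- intensities(ticNormalize(sb))
  sp <- oneVsRestSPlots(X, classLabels(sb), aOrtho = 1, scaling = "pareto")
  sel <- selectBiomarkers(sp, corrCut = 0.5, covQuantile = 0.8, m = 3)
  markers <- format(fuseMS:::binLabelsFor(100, 120, 0.2)[c(6, 27, 53)],
                    trim = TRUE)
  top <- unique(unlist(lapply(sel$perClass, head, 3)))
  expect_true(all(markers %in% top))
  # unreachable threshold selects nothing, with a warning not an error
  expect_warning(empty <- selectBiomarkers(sp, corrCut = 1.01),
                 "empty selection")
  expect_true(all(lengths(empty$perClass) == 0L))
  # consensus logic on constructed S-plots
  mk <- function(v, p) data.frame(variable = v, p1 = p, pcorr1 = p)
  fake <- list(A = mk(c("x", "y"), c(.9, .1)), B = mk(c("x", "y"), c(.95, .2)),
               C = mk(c("x", "y"), c(.85, .15)), D = mk(c("x", "y"), c(.1, .9)))
  sel2 <- selectBiomarkers(fake, corrCut = 0.5, covQuantile = 0, m = 3)
  expect_equal(sel2$consensus, "x")
})
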