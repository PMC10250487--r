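test_that("unstratified five-fold partition of 522 samples gives the expected sizes", {
  set.seed(61)
  y <- factor(rep_len(letters[1:5], 522))
  ad <- knnClassifier(1)
  X <- matrix(rnorm(522 * 2), 522, 2)
  cv <- kfoldCV(ad, X, y, folds = 5, stratified = FALSE, seed = 1)
  expect_equal(as.integer(sort(table(cv@foldAssign))),
               c(104L, 104L, 104L, 105L, 105L))
})

test_that("cross-validation is stratified, deterministic and leak-free", {
  set.seed(62)
  X <- rbind(matrix(rnorm(60, 0), 30, 2), matrix(rnorm(60, 5), 30, 2))
  y <- factor(rep(c("a", "b"), each = 30))
  ad <- knnClassifier(3)
  cv <- kfoldCV(ad, X, y, folds = 5, seed = 7)
  # stratified: every fold holds both classes
  for (f in 1:5) expect_setequal(unique(as.character(y[cv@foldAssign == f])),
                                 c("a", "b"))
  expect_identical(confusionMatrix(kfoldCV(ad, X, y, folds = 5, seed = 7)),
                   confusionMatrix(cv))
  # no leakage: refitting on the complement reproduces the stored fold
  # predictions exactly
  te <- cv@foldAssign == 1
  fit <- ad$fit(X[!te, , drop = FALSE], y[!te])
  expect_equal(as.character(ad$predict(fit, X[te, , drop = FALSE])),
               cv@predictions[te])
  expect_equal(unname(rowSums(confusionMatrix(cv))),
               unname(table(y)), ignore_attr = TRUE)
  expect_error(kfoldCV(ad, X, y, folds = 40, seed = 1), "stratification")
})

test_that("separable data reach 100% and permuted labels fall to chance", {
  set.seed(63)
  n <- 30
  X <- do.call(rbind, lapply(0:4, function(k)
    matrix(rnorm(2 * n, 8 * k), n, 2)))
  y <- factor(rep(letters[1:5], each = n))
  cv <- kfoldCV(knnClassifier(3), X, y, folds = 5, seed = 3)
  expect_equal(overallRate(cv), 100)
  set.seed(64)
  yp <- sample(y)
  band <- 100 * (0.2 + c(-3, 3) * sqrt(0.2 * 0.8 / length(yp)))
  for (ad in list(knnClassifier(5), plsdaClassifier(2), pcaLdaClassifier(2))) {
    r <- overallRate(kfoldCV(ad, X, yp, folds = 5, seed = 4))
    expect_gt(r, band[1])
    expect_lt(r, band[2])
  }
})

test_that("outlier flags catch gross outliers and calibrate to alpha", {
  set.seed(65)
  X <- matrix(rnorm(2000 * 5), 2000, 5)
  m <- suppressWarnings(nipalsPCA(X, 2))
  rate <- mean(flagOutliers(m, X, alpha = 0.05))
  expect_gt(rate, 0.035); expect_lt(rate, 0.065)
  expect_false(flagOutliers(m, matrix(colMeans(X), 1), alpha = 0.05))
  expect_true(flagOutliers(m, matrix(100 * apply(X, 2, max), 1),
                           alpha = 0.05))
})

test_that("replicated test samples are called by majority over non-outliers", {
  pred4v2 <- factor(c(rep("a", 4), rep("b", 2)), levels = c("a", "b"))
  rep6 <- function(p) function(X) p
  r <- evaluateTestSamples(rep6(pred4v2), matrix(0, 6, 1), rep(1, 6), "a")
  expect_equal(r$call, "a")
  expect_equal(r$accuracy, 100)
  # all replicates flagged: the sample call is "Outlier"
  r2 <- evaluateTestSamples(rep6(pred4v2), matrix(0, 6, 1), rep(1, 6), "a",
                            outlierFun = function(X) rep(TRUE, 6))
  expect_equal(r2$call, "Outlier")
  expect_equal(r2$accuracy, 0)
  expect_error(evaluateTestSamples(rep6(pred4v2), matrix(0, 6, 1),
                                   c(1, 1, 1, 2, 2, 3), c("a", "b", "c")),
               "replicate count")
})

test_that("the fused pipeline identifies replicated held-out samples", {
  ds <- smallDataset(nPerClass = 15, seed = 66)
  blocks <- asBlocks(ds)
  ad <- fusionClassifier(plsdaClassifier(10), scaling = c("pareto", "uv"))
  set.seed(66)
  fit <- suppressWarnings(ad$fit(blocks, ds$labels))
  test <- list(reims = intensities(ticNormalize(ds$test$spectra)),
               icpms = intensities(ds$test$elements))
  tr <- evaluateTestSamples(function(b) ad$predict(fit, b), test,
                            ds$test$sampleOf, as.character(ds$test$declared))
  expect_equal(tr$accuracy, 100)
})

test_that("Kruskal-Wallis matches the rank formula and a permutation oracle", {
  expect_equal(kruskalWallis(list(c(1, 1), c(1, 1, 1))),
               list(H = 0, p = 1, df = 1L))
  k <- kruskalWallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(k$H, 3.857, tolerance = 1e-3)
  expect_equal(k$df, 1)
  # significance-region case on two groups of 8: the chi-square tail is
  # close to the exhaustive permutation oracle
  g1 <- c(-2.19, -2.12, -0.95, -0.67, -0.60, -0.20, 0.48, 0.93)
  g2 <- c(-0.75, -0.17, 0.23, 0.41, 0.73, 0.85, 1.00, 1.02)
  expect_lt(abs(kruskalWallis(list(g1, g2))$p - permKWp(g1, g2)), 0.02)
  # invariance under strictly monotone transforms
  expect_equal(kruskalWallis(list(exp(g1), exp(g2)))$H,
               kruskalWallis(list(g1, g2))$H, tolerance = 1e-12)
  expect_error(kruskalWallis(list(1:3)), "length")
})

test_that("pairwise Mann-Whitney p-values match enumeration and flag separation", {
  g1 <- c(1.2, 3.4, 5.1, 7.9); g2 <- c(2.3, 4.5, 6.2, 8.8)
  pm <- pairwiseCompare(list(A = g1, B = g2), correction = "none")
  expect_equal(pm["A", "B"], permMWp(g1, g2), tolerance = 0.02)
  expect_equal(diag(pm), c(A = 1, B = 1))
  expect_equal(pm, t(pm))
  set.seed(67)
  far <- list(A = rnorm(50, 0), B = rnorm(50, 5), C = rnorm(50, 0.2))
  pf <- pairwiseCompare(far)
  expect_lt(pf["A", "B"], 0.001)
  expect_gt(pf["A", "C"], 0.01)
})

test_that("heatmap matrix is the min-max-scaled group-mean table", {
  conc <- rbind(c(10, 1), c(12, 1), c(2, 1), c(4, 1))
  colnames(conc) <- c("Fe", "Cu")
  eb <- ElementBlock(conc, class = c("w", "w", "f", "f"))
  hm <- heatmapMatrix(eb)
  expect_equal(hm["w", "Fe"], 1)
  expect_equal(hm["f", "Fe"], 0)
  expect_equal(unname(hm[, "Cu"]), c(0, 0))    # constant element
  expect_true(all(hm >= 0 & hm <= 1))
})

test_that("CV-ANOVA separates predictive from null models", {
  set.seed(68)
  n <- 24
  y <- factor(rep_len(c("a", "b"), n))
  X <- matrix(rnorm(n * 4), n, 4)
  X[, 1] <- X[, 1] + ifelse(y == "a", 4, -4)
  strong <- cvAnova(X, y, a = 1, folds = 4, seed = 5, nPerm = 49)
  expect_lt(strong$p, 0.001)
  expect_equal(strong$permP, 1 / 50)     # resolution floor 1/(nPerm+1)
  null <- cvAnova(matrix(rnorm(n * 4), n, 4), y, a = 1, folds = 4,
                  seed = 5, nPerm = 49)
  expect_gt(null$permP, 0.05)
})
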