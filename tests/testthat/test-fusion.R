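test_that("block compression picks k by cumulative variance with caps", {
  set.seed(41)
  u <- rnorm(10); v <- rnorm(6)
  r1 <- compressBlock(outer(u, v) +
                        sweep(matrix(0, 10, 6), 2, rnorm(6), "+"),
                      threshold = 0.5, scaling = "none")
  expect_equal(r1$compression@k, 1L)
  expect_equal(sum(r1$compression@varExplained), 1, tolerance = 1e-9)

  X <- matrix(rnorm(12 * 5), 12, 5)
  rfull <- compressBlock(X, threshold = 1, scaling = "none")
  expect_equal(rfull$compression@k, 5L)

  # engineered spectrum: 8 components reach exactly 85%
  set.seed(42)
  n <- 40; p <- 20
  d <- c(rep(sqrt(0.85 / 8), 8), rep(sqrt(0.15 / 12), 12))
  # score directions orthogonal to the ones vector, so centering is a no-op
  U <- qr.Q(qr(cbind(1, matrix(rnorm(n * p), n, p))))[, 2:(p + 1)]
  V <- qr.Q(qr(matrix(rnorm(p * p), p, p)))
  X8 <- U %*% diag(d) %*% t(V)
  r8 <- compressBlock(X8, threshold = 0.85, scaling = "none")
  expect_equal(r8$compression@k, 8L)
  expect_error(compressBlock(matrix(3, 6, 2), scaling = "none"),
               "degenerate-input")
})

test_that("compression scores are centered, orthogonal and projectable", {
  set.seed(43)
  X <- matrix(rnorm(25 * 12), 25, 12,
              dimnames = list(paste0("s", 1:25), NULL))
  cb <- compressBlock(X, threshold = 0.9, scaling = "pareto")
  s <- cb$scores
  expect_lt(max(abs(colMeans(s))), 1e-10)
  g <- crossprod(s)
  expect_lt(max(abs(g - diag(diag(g)))), 1e-8)
  expect_equal(compressionScores(cb$compression, X), s, tolerance = 1e-10)
  mu <- matrix(colMeans(X), 1)
  expect_lt(max(abs(compressionScores(cb$compression, mu))), 1e-10)
  expect_error(compressionScores(cb$compression, X[, 1:5]), "alignment")
})

test_that("low-level fusion concatenates min-max-scaled blocks", {
  set.seed(44)
  a <- matrix(rnorm(8 * 5500), 8, 5500, dimnames = list(paste0("s", 1:8), NULL))
  b <- matrix(rnorm(8 * 20), 8, 20, dimnames = list(paste0("s", 1:8), NULL))
  fm <- lowLevelFuse(list(reims = a, icpms = b))
  expect_equal(ncol(fusedMatrix(fm)), 5520L)
  expect_true(all(fusedMatrix(fm) >= 0 & fusedMatrix(fm) <= 1))
  expect_equal(unname(table(provenance(fm)$block)[c("reims", "icpms")]),
               c(5500L, 20L), ignore_attr = TRUE)
  one <- lowLevelFuse(list(only = b))
  expect_equal(fusedMatrix(one), minmaxScale(b), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(lowLevelFuse(list(a = a, b = b[1:4, ])), "alignment")
})

test_that("mid-level fusion width is the sum of per-block components", {
  set.seed(45)
  a <- matrix(rnorm(240 * 300), 240, 300)
  b <- matrix(rnorm(240 * 20), 240, 20)
  fm <- midLevelFuse(list(reims = a, icpms = b), k = c(226, 8),
                     scaling = c("pareto", "uv"))
  expect_equal(ncol(fusedMatrix(fm)), 234L)
  pv <- provenance(fm)
  expect_equal(sum(pv$block == "reims"), 226L)
  expect_equal(sum(pv$block == "icpms"), 8L)
  expect_equal(anyDuplicated(pv$feature), 0L)
  one <- midLevelFuse(list(x = b), threshold = 0.85, scaling = "uv")
  cb <- compressBlock(b, threshold = 0.85, scaling = "uv", blockName = "x")
  expect_equal(fusedMatrix(one), cb$scores, tolerance = 1e-10)
})

test_that("projection reproduces training rows and places held-out samples", {
  ds <- smallDataset(nPerClass = 12, seed = 46)
  blocks <- asBlocks(ds)
  fm <- midLevelFuse(blocks, scaling = c("pareto", "uv"))
  expect_equal(projectSamples(fm, blocks), fusedMatrix(fm),
               tolerance = 1e-10, ignore_attr = TRUE)
  # held-out replicates land nearest their generating class centroid
  test <- list(reims = intensities(ticNormalize(ds$test$spectra)),
               icpms = intensities(ds$test$elements))
  pr <- projectSamples(fm, test)
  cent <- apply(fusedMatrix(fm), 2, function(v) tapply(v, ds$labels, mean))
  nearest <- apply(pr, 1, function(r)
    rownames(cent)[which.min(colSums((t(cent) - r)^2))])
  expect_gt(mean(nearest == as.character(ds$test$labels)), 0.95)
  expect_error(projectSamples(fm, blocks["reims"]), "alignment")
})

test_that("block order permutes provenance but not downstream accuracy", {
  ds <- smallDataset(nPerClass = 10, seed = 47)
  blocks <- asBlocks(ds)
  ad12 <- fusionClassifier(plsdaClassifier(5), scaling = c("pareto", "uv"))
  ad21 <- fusionClassifier(plsdaClassifier(5), scaling = c("uv", "pareto"))
  cv12 <- suppressWarnings(kfoldCV(ad12, blocks, ds$labels, folds = 5, seed = 1))
  cv21 <- suppressWarnings(kfoldCV(ad21, rev(blocks), ds$labels, folds = 5,
                                   seed = 1))
  expect_equal(overallRate(cv12), overallRate(cv21))
})

test_that("fused accuracy is at least the best single block", {
  ds <- smallDataset(nPerClass = 20, seed = 48)
  blocks <- asBlocks(ds)
  rate <- function(bl, sc) overallRate(suppressWarnings(
    kfoldCV(fusionClassifier(plsdaClassifier(10), scaling = sc), bl,
            ds$labels, folds = 5, seed = 2)))
  fusedRate <- rate(blocks, c("pareto", "uv"))
  expect_gte(fusedRate, max(rate(blocks["reims"], "pareto"),
                            rate(blocks["icpms"], "uv")))
})
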