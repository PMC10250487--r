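test_that("lockmass correction is a single-point multiplicative recalibration", {
  pk <- PeakList(c(200, 600), c(1, 2))
  expect_equal(lockmassCorrect(pk, 554.2615)@mz, pk@mz)   # no drift
  corr <- lockmassCorrect(PeakList(600, 1), 554.3000)
  expect_equal(corr@mz, 600 * 554.2615 / 554.3000, tolerance = 1e-12)
  expect_equal(round(corr@mz, 4), 599.9583)
  expect_error(lockmassCorrect(pk, -1), "calibration")
  expect_error(lockmassCorrect(pk), "calibration")
})

test_that("lockmass correction exactly inverts a uniform drift from the generator", {
  cfg <- simConfig(nPerClass = 2, seed = 3, hi = 120, massDrift = 1e-4,
                   testSamples = 2, testReplicates = 1)
  noEffects <- defaultMarkerEffects()[0, ]
  set.seed(3)
  drifted <- sampleSpectraBlock(cfg, effects = noEffects, asPeakLists = TRUE)
  d <- attr(drifted, "driftFactor")
  corrected <- lockmassCorrect(drifted[[1]], observedLock = 554.2615 * d)
  set.seed(3)
  clean <- sampleSpectraBlock(simConfig(nPerClass = 2, seed = 3, hi = 120,
                                        testSamples = 2, testReplicates = 1),
                              effects = noEffects, asPeakLists = TRUE)
  expect_equal(corrected@mz, clean[[1]]@mz, tolerance = 1e-9)
  # and bin assignments are restored exactly
  expect_equal(as.numeric(binSpectrum(corrected, 100, 120, 0.2)),
               as.numeric(binSpectrum(clean[[1]], 100, 120, 0.2)))
})

test_that("background subtraction clips at zero and ignores unmatched peaks", {
  s <- PeakList(c(300, 400), c(5, 2))
  expect_equal(backgroundSubtract(s, s)@intensity, c(0, 0))
  empty <- PeakList(numeric(0), numeric(0))
  expect_equal(backgroundSubtract(s, empty)@intensity, s@intensity)
  b <- PeakList(300, 7)
  expect_equal(backgroundSubtract(s, b)@intensity, c(0, 2))
  expect_error(backgroundSubtract(s, PeakList(300, 7, lo = 0, hi = 500)),
               "ranges differ")
})

test_that("TIC threshold removes peaks below the input-TIC fraction", {
  pk <- PeakList(c(200, 300, 400), c(10, 1, 1e-4))
  expect_equal(ticThresholdFilter(pk, 0)@intensity, pk@intensity)
  kept <- ticThresholdFilter(pk, 1e-5)
  expect_equal(length(kept@mz), 2L)   # the 1e-4 peak is below 1.1e-4
  for (n in 2:6) {                    # equal peaks survive fraction < 1/n
    eq <- PeakList(seq(200, 200 + n - 1), rep(3, n))
    expect_equal(length(ticThresholdFilter(eq, 1 / n - 1e-9)@mz), n)
  }
})

test_that("binning uses half-open 0.2-Da bins with centre labels", {
  v <- binSpectrum(PeakList(327.2324, 1))
  expect_length(v, 5500L)
  expect_equal(unname(which(v > 0)), 1137L)   # bin index 1136 zero-based
  expect_equal(attr(v, "labels")[1137], 327.3)
  edge <- binSpectrum(PeakList(c(100, 1199.9999), c(1, 2)))
  expect_equal(unname(edge[1]), 1)
  expect_equal(unname(edge[5500]), 2)
  expect_equal(attr(binSpectrum(PeakList(99, 1)), "dropped"), 1L)
  expect_error(binSpectrum(PeakList(200, 1), width = 0.3), "divide")
})

test_that("binning conserves total in-range intensity on random peak lists", {
  for (s in 1:5) {
    pk <- randomPeaks(200, lo = 50, hi = 1300, seed = s)
    v <- binSpectrum(pk)
    inr <- pk@mz >= 100 & pk@mz < 1200
    expect_equal(sum(v), sum(pk@intensity[inr]), tolerance = 1e-12)
    expect_equal(attr(v, "dropped"), sum(!inr))
  }
})

test_that("the spectral chain is stable under permutation of peak order", {
  set.seed(9)
  pk <- randomPeaks(300, seed = 9)
  bg <- randomPeaks(50, seed = 10)
  chain <- function(p) {
    p <- backgroundSubtract(p, bg)
    p <- lockmassCorrect(p, 554.30)
    p <- ticThresholdFilter(p, 1e-4)
    binSpectrum(p)
  }
  perm <- sample(length(pk@mz))
  pk2 <- PeakList(pk@mz[perm], pk@intensity[perm])
  expect_equal(chain(pk), chain(pk2), tolerance = 1e-12)
})

test_that("TIC normalisation makes rows sum to one and names bad samples", {
  m <- matrix(c(2, 2, 1, 3), 2, 2, byrow = TRUE,
              dimnames = list(c("a", "b"), NULL))
  sb <- SpectraBlock(cbind(m, matrix(0, 2, 5498)), 100, 1200, 0.2)
  tn <- ticNormalize(sb)
  expect_equal(unname(rowSums(intensities(tn))), c(1, 1), tolerance = 1e-12)
  expect_equal(unname(intensities(tn)[1, 1:2]), c(0.5, 0.5))
  bad <- SpectraBlock(matrix(0, 1, 5500, dimnames = list("S7", NULL)))
  expect_error(ticNormalize(bad), "S7")
})

test_that("min-max scaling stores extrema and projects held-out data unclipped", {
  x <- matrix(c(2, 4, 6, 3, 3, 3), 3, 2)
  sc <- minmaxScale(x)
  expect_equal(sc[, 1], c(0, 0.5, 1))
  expect_equal(sc[, 2], c(0, 0, 0))            # constant column maps to 0
  fit <- attr(sc, "fit")
  expect_equal(applyMinMax(fit, x), sc, ignore_attr = TRUE)
  held <- applyMinMax(fit, matrix(c(8, 3), 1, 2))
  expect_gt(held[1, 1], 1)                      # no clipping beyond the max
  set.seed(2)
  r <- matrix(rnorm(40), 8, 5)
  expect_true(all(minmaxScale(r) >= 0 & minmaxScale(r) <= 1))
})

test_that("internal-standard ratioing cancels sensitivity drift", {
  m <- matrix(c(10, 20), 1, 2)
  expect_equal(internalStandardNormalize(m, 1), m)
  expect_equal(unname(internalStandardNormalize(m, 2)),
               matrix(c(5, 10), 1, 2))
  set.seed(4)
  x <- matrix(rlnorm(30), 5, 6, dimnames = list(paste0("s", 1:5), NULL))
  is0 <- rlnorm(5)
  drift <- 2
  expect_equal(internalStandardNormalize(x * drift, is0 * drift),
               internalStandardNormalize(x, is0), tolerance = 1e-12)
  expect_error(internalStandardNormalize(x, c(1, 1, 0, 1, 1)), "s3")
})

test_that("CRM recovery reports mean recovery, RSD and pass flags", {
  cert <- c(A = 100, B = 50)
  ctrl <- rbind(c(100, 50), c(100, 50))
  colnames(ctrl) <- names(cert)
  r <- crmCheck(ctrl, cert)
  expect_equal(r$meanRecovery, c(100, 100))
  expect_equal(r$rsd, c(0, 0))
  expect_true(all(r$pass))
  r2 <- crmCheck(rbind(c(50, 50), c(50, 50)), cert)
  expect_false(r2$pass[1])
  expect_equal(r2$meanRecovery[1], 50)
  # drifting worklist: stats agree with direct computation
  ctrl3 <- rbind(c(95, 48), c(105, 52.8))
  r3 <- crmCheck(ctrl3, cert)
  expect_equal(r3$rsd, 100 * apply(ctrl3, 2, sd) / colMeans(ctrl3),
               ignore_attr = TRUE)
  expect_error(crmCheck(ctrl[1, , drop = FALSE], cert), "two control")
  expect_error(crmCheck(ctrl, c(A = 0, B = 50)), "zero certified")
})

test_that("element filtering drops below-LOD and excluded panels", {
  survivors <- c("Li", "B", "Al", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu",
                 "Zn", "As", "Se", "Rb", "Sr", "Nb", "Mo", "Cd", "Cs", "Ta")
  extra <- c("Na", "K", "Hg")                   # high-concentration screen
  censored <- c("Be", "U")                      # below LOD everywhere
  all <- c(survivors, extra, censored)
  set.seed(5)
  conc <- matrix(rlnorm(6 * length(all)), 6, length(all),
                 dimnames = list(NULL, all))
  conc[, censored] <- 0
  eb <- ElementBlock(conc)
  kept <- filterElements(eb, exclude = extra)
  expect_setequal(elementNames(kept), survivors)
  expect_length(elementNames(kept), 20L)
  expect_setequal(elementNames(filterElements(eb, maxBelowLodFraction = 1)),
                  all)
  conc2 <- conc; conc2[, ] <- 0
  expect_error(filterElements(ElementBlock(conc2)), "empty-panel")
})
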