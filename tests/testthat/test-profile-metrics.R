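# Key points, cosine similarity, discrete Frechet distance.

test_that("key points of a unit triangle match the closed-form crossings", {
  tri <- TorqueProfile(GaitCurve(c(0, 50, 100), c(0, 1, 0), "gait",
                                 "assistive_torque"), controller = "FS")
  kp <- keyPoints(tri, 0.039)
  expect_equal(onsetPercent(kp), 1.95)
  expect_equal(peakPercent(kp), 50)
  expect_equal(offsetPercent(kp), 98.05)
  expect_equal(peakValue(kp), 1)
})

test_that("key-point timings are scale invariant and interpolated sub-grid", {
  set.seed(8)
  for (i in 1:10) {
    p <- randomProfile(101L)
    kp1 <- keyPoints(p, 0.1)
    kp2 <- keyPoints(applyScaleFactor(p, runif(1, 0.01, 20)), 0.1)
    expect_equal(onsetPercent(kp1), onsetPercent(kp2))
    expect_equal(offsetPercent(kp1), offsetPercent(kp2))
  }
  # crossings are not snapped to the 1% grid
  ph <- seq(0, 100, by = 1)
  p <- TorqueProfile(GaitCurve(ph, pmax(0, 1 - abs(ph - 50) / 30), "stance",
                               "assistive_torque"), controller = "DB")
  kp <- keyPoints(p, 0.05)
  expect_false(onsetPercent(kp) == round(onsetPercent(kp)))
})

test_that("onset anchors to the main lobe of a multi-lobed profile", {
  ph <- seq(0, 100, by = 1)
  v <- pmax(0, 0.3 - abs(ph - 15) / 20) +      # early secondary lobe
       pmax(0, 1 - abs(ph - 70) / 15)          # main lobe
  p <- TorqueProfile(GaitCurve(ph, v, "stance", "assistive_torque"),
                     controller = "DB")
  kp <- keyPoints(p, 0.088)
  expect_equal(peakPercent(kp), 70)
  expect_gt(onsetPercent(kp), 40)  # onset is the last up-crossing before 70
})

test_that("keyPoints errors on profiles with no positive maximum", {
  flat <- TorqueProfile(GaitCurve(c(0, 100), c(0, 0), "stance",
                                  "assistive_torque"), controller = "FS")
  expect_error(keyPoints(flat), "no positive maximum")
})

test_that("cosine similarity: identity, orthogonality, scale invariance", {
  p <- randomProfile(101L)
  expect_equal(cosineSimilarity(p, p), 1)
  ph <- seq(0, 100, by = 1)
  a <- TorqueProfile(GaitCurve(ph, as.numeric(ph < 40), "stance",
                               "assistive_torque"), controller = "FS")
  b <- TorqueProfile(GaitCurve(ph, as.numeric(ph > 60), "stance",
                               "assistive_torque"), controller = "DB")
  expect_equal(cosineSimilarity(a, b), 0)  # disjoint supports
  q <- randomProfile(101L)
  expect_equal(cosineSimilarity(applyScaleFactor(p, 3.7), q),
               cosineSimilarity(p, q))
  zero <- TorqueProfile(GaitCurve(ph, rep(0, 101), "stance",
                                  "assistive_torque"), controller = "FS")
  expect_error(cosineSimilarity(p, zero), "all-zero")
})

test_that("comparisons refuse mismatched grids and phase kinds", {
  p <- randomProfile(101L, phaseKind = "stance")
  g <- randomProfile(101L, phaseKind = "gait")
  expect_error(cosineSimilarity(p, g), "phase kinds")
  short <- randomProfile(51L, phaseKind = "stance")
  expect_error(frechetDistance(p, short), "share one phase grid")
})

test_that("frechetDistance: identity, constant offset, scale sensitivity", {
  p <- randomProfile(101L)
  expect_equal(frechetDistance(p, p), 0)
  ph <- seq(0, 100, by = 1)
  c0 <- TorqueProfile(GaitCurve(ph, rep(0.5, 101), "stance",
                                "assistive_torque"), controller = "FS")
  ch <- TorqueProfile(GaitCurve(ph, rep(1.8, 101), "stance",
                                "assistive_torque"), controller = "DB")
  expect_equal(frechetDistance(c0, ch), 1.3)  # equal-phase couplings
  # NOT invariant under rescaling (cosine similarity is)
  q <- randomProfile(101L)
  expect_false(isTRUE(all.equal(frechetDistance(applyScaleFactor(p, 5), q),
                                frechetDistance(p, q))))
})

test_that("DP Frechet equals the exhaustive coupling minimum on small curves", {
  set.seed(101)
  for (trial in 1:200) {
    n <- sample(2:7, 1)
    m <- sample(2:7, 1)
    ph1 <- sort(runif(n, 0, 100))
    ph2 <- sort(runif(m, 0, 100))
    v1 <- runif(n, 0, 2)
    v2 <- runif(m, 0, 2)
    a <- GaitCurve(ph1, v1, "stance", "assistive_torque")
    b <- GaitCurve(ph2, v2, "stance", "assistive_torque")
    dp <- soleusExo:::.frechetDP(phasePoints(a), v1, phasePoints(b), v2)
    expect_equal(dp, bruteFrechet(phasePoints(a), v1, phasePoints(b), v2),
                 tolerance = 1e-12)
  }
})

test_that("Frechet distance is a metric-like: endpoint bound, symmetry, triangle", {
  set.seed(55)
  mk <- function() {
    n <- 8L
    GaitCurve(seq(0, 100, length.out = n), runif(n, 0, 2), "stance",
              "assistive_torque")
  }
  for (trial in 1:50) {
    a <- mk(); b <- mk(); cc <- mk()
    dab <- frechetDistance(a, b)
    ea <- sqrt((curveValues(a)[1] - curveValues(b)[1])^2)
    eb <- sqrt((curveValues(a)[8] - curveValues(b)[8])^2)
    expect_gte(dab + 1e-12, max(ea, eb))  # endpoints must be coupled
    expect_equal(dab, frechetDistance(b, a))
    expect_lte(dab, frechetDistance(a, cc) + frechetDistance(cc, b) + 1e-12)
  }
})

test_that("similarityReport bundles both measures with the grid size", {
  p <- randomProfile(101L)
  q <- randomProfile(101L)
  rep <- similarityReport(p, q)
  expect_equal(rep@cosineSimilarity, cosineSimilarity(p, q))
  expect_equal(rep@frechetDistance, frechetDistance(p, q))
  expect_identical(rep@nPoints, 101L)
})
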