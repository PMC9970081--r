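# Ingestion, resampling and stance/gait re-normalisation.

test_that("GaitCurve validity enforces the axis and finiteness invariants", {
  expect_s4_class(GaitCurve(c(0, 50, 100), c(0, 1, 0), "stance", "joint_torque"),
                  "GaitCurve")
  expect_error(GaitCurve(c(0, 50, 40), c(0, 1, 0), "stance", "joint_torque"),
               "strictly increasing")
  expect_error(GaitCurve(c(0, 50), c(0, 1, 0), "stance", "joint_torque"),
               "same length")
  expect_error(GaitCurve(c(0), c(1), "stance", "joint_torque"), "at least 2")
  expect_error(GaitCurve(c(-1, 50), c(0, 1), "stance", "joint_torque"),
               "within \\[0, 100\\]")
  expect_error(GaitCurve(c(0, NA), c(0, 1), "stance", "joint_torque"), "finite")
})

test_that("readCurveTable parses valid tables and rejects bad rows by number", {
  f <- writeCsvFixture(data.frame(phase = c(0, 50, 100), torque = c(0, 1, 0)))
  gc <- readCurveTable(f, "torque", "joint_torque", "stance")
  expect_length(phasePoints(gc), 3L)
  expect_identical(curveValues(gc), c(0, 1, 0))

  bad <- writeCsvFixture(data.frame(phase = c(0, 50, 40), v = c(0, 1, 0)))
  expect_error(readCurveTable(bad, "v", "joint_torque", "stance"), "row 3")

  nf <- writeCsvFixture(data.frame(phase = c(0, 50, 100), v = c(0, NA, 0)))
  expect_error(readCurveTable(nf, "v", "joint_torque", "stance"), "row 2")

  expect_error(readCurveTable(f, "missing", "joint_torque", "stance"),
               "column 'missing'")
  expect_error(readCurveTable(tempfile(), "v", "joint_torque", "stance"),
               "does not exist")
})

test_that("negate flag flips digitized sign conventions at ingestion", {
  f <- writeCsvFixture(data.frame(phase = c(0, 50, 100), vel = c(0.1, 0.5, -0.2)))
  gc <- readCurveTable(f, "vel", "fascicle_velocity", "stance", negate = TRUE)
  expect_identical(curveValues(gc), c(-0.1, -0.5, 0.2))
})

test_that("ingestion fuzz: random valid tables yield valid curves, corrupted ones error", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(3:40, 1)
    ph <- sort(runif(n, 0, 100))
    while (any(diff(ph) <= 0)) ph <- sort(runif(n, 0, 100))
    v <- rnorm(n)
    f <- writeCsvFixture(data.frame(phase = ph, v = v))
    gc <- readCurveTable(f, "v", "tendon_velocity", "gait")
    expect_true(validObject(gc))
    # corrupt one cell or the monotonicity and expect rejection
    bad <- data.frame(phase = ph, v = v)
    if (i %% 2 == 0) bad$v[sample(n, 1)] <- NA else {
      j <- sample(2:n, 1)
      bad$phase[j] <- bad$phase[j - 1L]
    }
    expect_error(readCurveTable(writeCsvFixture(bad), "v", "tendon_velocity",
                                "gait"))
  }
})

test_that("resample interpolates linearly on the inclusive 0-100 grid", {
  gc <- GaitCurve(c(0, 100), c(0, 10), "stance", "joint_torque")
  r <- resample(gc, 101L)
  expect_identical(phasePoints(r), seq(0, 100, by = 1))
  expect_equal(curveValues(r)[51], 5)

  uniform <- GaitCurve(seq(0, 100, by = 1), sin(seq(0, 100, by = 1) / 7),
                       "stance", "joint_torque")
  expect_equal(resample(uniform, 101L), uniform)

  # endpoint hold outside the source phase range
  held <- resample(GaitCurve(c(10, 90), c(1, 1), "stance", "joint_torque"), 101L)
  expect_true(all(curveValues(held) == 1))

  expect_error(resample(gc, 1L), "at least 2")
})

test_that("resample preserves extrema of piecewise-linear curves at shared knots", {
  set.seed(7)
  for (i in 1:10) {
    knots <- seq(0, 100, by = 10)  # knots on the 1% grid => shared with output
    v <- rnorm(length(knots))
    gc <- GaitCurve(knots, v, "stance", "joint_torque")
    r <- resample(gc, 101L)
    expect_equal(max(curveValues(r)), max(v))
    expect_equal(min(curveValues(r)), min(v))
  }
})

test_that("stanceToGait scales the phase axis by toe-off and flips the kind", {
  gc <- GaitCurve(c(0, 50, 100), c(1, 2, 3), "stance", "joint_torque")
  g <- stanceToGait(gc, 62.7)
  expect_identical(phaseKind(g), "gait")
  expect_equal(phasePoints(g), c(0, 31.35, 62.7))
  expect_identical(curveValues(g), curveValues(gc))
  expect_equal(phasePoints(stanceToGait(gc, 100)), phasePoints(gc))
  expect_error(stanceToGait(g, 62.7), "stance-kind")
})

test_that("stanceToGait then gaitToStance recovers the phase axis", {
  set.seed(11)
  for (toeOff in c(30, 62.7, 95, 100)) {
    ph <- sort(sample(0:100, 12))
    gc <- GaitCurve(ph, rnorm(12), "stance", "fascicle_velocity")
    back <- gaitToStance(stanceToGait(gc, toeOff), toeOff)
    expect_equal(phasePoints(back), phasePoints(gc), tolerance = 1e-12)
    expect_identical(curveValues(back), curveValues(gc))
  }
})

test_that("MtuDynamics aligns mismatched axes onto the torque grid", {
  t <- GaitCurve(seq(0, 100, 10), pmax(0, sin(seq(0, 100, 10) / 30)),
                 "stance", "joint_torque")
  f <- GaitCurve(c(0, 60, 100), c(0, -1, 0), "stance", "fascicle_velocity")
  v <- GaitCurve(c(0, 30, 100), c(0.5, 1, -1), "stance", "tendon_velocity")
  dyn <- MtuDynamics(t, f, v, speed = 1.4, gaitType = "walk")
  expect_true(validObject(dyn))
  expect_identical(phasePoints(fascicleVelocity(dyn)), phasePoints(torqueCurve(dyn)))
  expect_equal(curveValues(fascicleVelocity(dyn))[7], -1)  # 60% is a torque knot
})
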