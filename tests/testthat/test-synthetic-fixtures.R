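# Synthetic dynamics generator: determinism, planted features, recovery.

test_that("identical configs give bitwise-identical dynamics", {
  a <- synthDynamics(SynthConfig("walk", 1.4, noiseSd = 0.02, seed = 7L))
  b <- synthDynamics(SynthConfig("walk", 1.4, noiseSd = 0.02, seed = 7L))
  expect_identical(curveValues(torqueCurve(a)), curveValues(torqueCurve(b)))
  expect_identical(curveValues(fascicleVelocity(a)),
                   curveValues(fascicleVelocity(b)))
  expect_identical(curveValues(tendonVelocity(a)),
                   curveValues(tendonVelocity(b)))
  c2 <- synthDynamics(SynthConfig("walk", 1.4, noiseSd = 0.02, seed = 8L))
  expect_false(identical(curveValues(torqueCurve(a)), curveValues(torqueCurve(c2))))
})

test_that("the generator leaves the global RNG state untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(synthDynamics(SynthConfig("run", 3.0, noiseSd = 0.05, seed = 1L)))
  expect_identical(.Random.seed, before)
})

test_that("noiseless planted torque peak is reproduced exactly", {
  cfg <- SynthConfig("walk", 1.4, torquePeakPhase = 46, torquePeakMag = 0.9)
  dyn <- synthDynamics(cfg)
  tq <- torqueCurve(dyn)
  expect_equal(max(curveValues(tq)), 0.9)
  expect_equal(phasePoints(tq)[which.max(curveValues(tq))], 46)
})

test_that("planted tendon peak and fascicle value set the deadband threshold", {
  cfg <- SynthConfig("walk", 1.4, tendonPeakPhase = 20)
  dyn <- synthDynamics(cfg)
  db <- deadbandSpeed(dyn)
  expect_equal(tendonPeakPhase(db), 20)
  # recompute by exhaustive scan, independent of which.max
  tv <- curveValues(tendonVelocity(dyn))
  i <- which(tv == max(tv))[1L]
  expect_equal(thresholdSpeed(db), abs(curveValues(fascicleVelocity(dyn))[i]))
})

test_that("the early-stance secondary fascicle mode adds a DB lobe", {
  cfg <- defaultControllerConfig("run")
  base <- SynthConfig("run", 5.0, secondaryMag = 0)
  dynOff <- synthDynamics(base)
  dynOn <- synthDynamics(SynthConfig("run", 5.0))  # secondary on by default at 5 m/s
  expect_gt(dynOn@fascicleVelocity@values[13] * -1,
            thresholdSpeed(deadbandSpeed(dynOn)))  # planted above the deadband
  dbOff <- dbProfile(dynOff, cfg)
  dbOn <- dbProfile(dynOn, cfg)
  expect_equal(countLobes(dbOn), countLobes(dbOff) + 1L)
  # the extra lobe sits in early stance
  ph <- phasePoints(dbOn)
  early <- ph <= 25
  expect_gt(max(curveValues(dbOn)[early]), 0)
  expect_equal(max(curveValues(dbOff)[early]), 0)
})

test_that("controller key points move monotonically with the planted feature phase", {
  cfgW <- defaultControllerConfig("walk")
  # FS peak tracks the planted torque peak phase
  fsPeaks <- vapply(c(60, 70, 80), function(pp) {
    dyn <- synthDynamics(SynthConfig("walk", 1.4, torquePeakPhase = pp))
    peakPercent(keyPoints(fsProfile(dyn, cfgW), cfgW@onsetFraction))
  }, numeric(1))
  expect_true(all(diff(fsPeaks) > 0))
  # DB peak tracks the planted fascicle-velocity peak phase
  dbPeaks <- vapply(c(75, 82, 88), function(pp) {
    dyn <- synthDynamics(SynthConfig("walk", 1.4, fasciclePeakPhase = pp))
    peakPercent(keyPoints(dbProfile(dyn, cfgW), cfgW@onsetFraction))
  }, numeric(1))
  expect_true(all(diff(dbPeaks) > 0))
})

test_that("key-point recovery degrades continuously as noise grows", {
  cfgW <- defaultControllerConfig("walk")
  clean <- synthDynamics(SynthConfig("walk", 1.4))
  kp0 <- keyPoints(fsProfile(clean, cfgW), cfgW@onsetFraction)
  errs <- vapply(c(0.001, 0.005, 0.02), function(sd) {
    e <- vapply(1:5, function(s) {
      dyn <- synthDynamics(SynthConfig("walk", 1.4, noiseSd = sd,
                                       seed = as.integer(100 + s)))
      kp <- keyPoints(fsProfile(dyn, cfgW), cfgW@onsetFraction)
      abs(peakPercent(kp) - peakPercent(kp0))
    }, numeric(1))
    mean(e)
  }, numeric(1))
  # small noise -> small error; no discontinuous failure below the ceiling
  expect_lt(errs[1], 2)
  expect_lt(errs[3], 10)
})

test_that("synthReference reproduces its knot values (delegation to hitlCurve)", {
  p <- HitlParams(20, 50, 62, 1, 0.039)
  prof <- synthReference(p)
  expect_equal(max(curveValues(prof)), 1)
  v <- curveValues(prof)[phasePoints(prof) == 20]
  expect_equal(v, 0.039)
  # planted-parameter recovery: onset/offset recovered within one grid cell
  kp <- keyPoints(prof, 0.039)
  expect_lt(abs(onsetPercent(kp) - 20), 1)
  # the fall has zero slope at offset, so the threshold crossing sits just
  # before the offset knot, never after it
  expect_lte(offsetPercent(kp), 62)
  expect_gt(offsetPercent(kp), 55)
  expect_equal(peakPercent(kp), 50)
})

test_that("SynthConfig validity rejects out-of-range parameters", {
  expect_error(SynthConfig("walk", 1.4, torquePeakPhase = 0), "\\(0, 100\\)")
  expect_error(SynthConfig("walk", 1.4, noiseSd = -0.1), "nonnegative")
  expect_error(SynthConfig("walk", 1.4, fasciclePeakMag = -1), "nonnegative")
})
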