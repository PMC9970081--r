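# FS and DB torque controllers: force conversion, deadband detection,
# profile construction, peak-matching calibration.

makeDyn <- function(torque, fascicle, tendon, phase = seq(0, 100, length.out = length(torque)),
                    speed = 1.4, gaitType = "walk") {
  MtuDynamics(GaitCurve(phase, torque, "stance", "joint_torque"),
              GaitCurve(phase, fascicle, "stance", "fascicle_velocity"),
              GaitCurve(phase, tendon, "stance", "tendon_velocity"),
              speed = speed, gaitType = gaitType)
}

test_that("mtuForce divides torque by the moment arm, preserving sign", {
  gc <- GaitCurve(c(0, 50, 100), c(1, 0, -0.5), "stance", "joint_torque")
  f <- mtuForce(gc, 0.042)
  expect_equal(f[1], 1 / 0.042, tolerance = 1e-12)  # ~23.81 N/kg
  expect_identical(f[2], 0)
  expect_lt(f[3], 0)
  expect_equal(mtuForce(gc, 0.021), 2 * f)
  expect_error(mtuForce(gc, 0), "positive")
  vel <- GaitCurve(c(0, 100), c(0, 1), "stance", "tendon_velocity")
  expect_error(mtuForce(vel), "joint_torque")
})

test_that("deadbandSpeed picks |fascicle| at the tendon-velocity maximum", {
  ph <- seq(0, 100, by = 1)
  tendon <- exp(-((ph - 20) / 10)^2)          # peak at 20%
  fascicle <- -0.4 + 0 * ph
  dyn <- makeDyn(pmax(0, sin(ph / 30)), fascicle, tendon)
  db <- deadbandSpeed(dyn)
  expect_equal(thresholdSpeed(db), 0.4)
  expect_equal(tendonPeakPhase(db), 20)

  # constant tendon velocity: earliest-index tie-break
  dyn2 <- makeDyn(pmax(0, sin(ph / 30)), -ph / 100, rep(1, length(ph)))
  expect_equal(tendonPeakPhase(deadbandSpeed(dyn2)), 0)
  expect_equal(thresholdSpeed(deadbandSpeed(dyn2)), 0)

  # all-nonpositive tendon velocity: warning, least-negative sample used
  dyn3 <- makeDyn(pmax(0, sin(ph / 30)), -ph / 100, -1 - abs(ph - 60) / 100)
  expect_warning(db3 <- deadbandSpeed(dyn3), "never positive")
  expect_equal(tendonPeakPhase(db3), 60)
})

test_that("fsProfile follows the force/velocity branch table", {
  ph <- seq(0, 100, by = 1)
  # negative force everywhere -> zero profile
  dyn <- makeDyn(rep(-0.5, 101), -ph / 100, sin(ph / 20))
  expect_true(all(curveValues(fsProfile(dyn)) == 0))
  # zero fascicle velocity everywhere -> zero profile regardless of force
  dyn2 <- makeDyn(pmax(0, sin(ph / 30)), rep(0, 101), sin(ph / 20))
  expect_true(all(curveValues(fsProfile(dyn2)) == 0))
  # eccentric samples get the extra 1/3.6 force discount
  cfg <- ControllerConfig(slowFiber = FiberParams(1, 2),
                          fastFiber = FiberParams(1, 2))
  dynC <- makeDyn(rep(1, 101), rep(-0.5, 101), sin(ph / 20))
  dynE <- makeDyn(rep(1, 101), rep(0.5, 101), sin(ph / 20))
  con <- curveValues(fsProfile(dynC, cfg))
  ecc <- curveValues(fsProfile(dynE, cfg))
  expect_equal(con, rep(0.5 / 0.042, 101))            # F * As_net
  expect_equal(ecc, con / 2.7 / 3.6)                  # both discounts
})

test_that("fsProfile is linear in torque; dbProfile ignores torque magnitude", {
  set.seed(21)
  ph <- seq(0, 100, by = 1)
  torque <- pmax(0, sin(ph / 32))
  fascicle <- -0.8 * exp(-((ph - 80) / 15)^2)
  tendon <- exp(-((ph - 25) / 12)^2) - exp(-((ph - 90) / 10)^2)
  for (k in c(0.5, 2, 7)) {
    d1 <- makeDyn(torque, fascicle, tendon)
    dk <- makeDyn(k * torque, fascicle, tendon)
    expect_equal(curveValues(fsProfile(dk)), k * curveValues(fsProfile(d1)))
    expect_equal(curveValues(dbProfile(dk)), curveValues(dbProfile(d1)))
  }
})

test_that("halving the moment arm rescales FS uniformly (shape invariant)", {
  ph <- seq(0, 100, by = 1)
  dyn <- makeDyn(pmax(0, sin(ph / 32)), -0.8 * exp(-((ph - 80) / 15)^2),
                 exp(-((ph - 25) / 12)^2))
  a <- curveValues(fsProfile(dyn, ControllerConfig(momentArm = 0.042)))
  b <- curveValues(fsProfile(dyn, ControllerConfig(momentArm = 0.021)))
  expect_equal(b, 2 * a)
})

test_that("both controllers are zero wherever force is negative", {
  ph <- seq(0, 100, by = 1)
  torque <- sin(ph / 16)  # alternating sign
  dyn <- makeDyn(torque, -0.5 - ph / 200, exp(-((ph - 25) / 12)^2))
  neg <- torque < 0
  expect_true(all(curveValues(fsProfile(dyn))[neg] == 0))
  expect_true(all(curveValues(dbProfile(dyn, threshold = 0))[neg] == 0))
})

test_that("dbProfile zeroes the deadbanded region and honors degenerate thresholds", {
  ph <- seq(0, 100, by = 1)
  fascicle <- -0.3 * exp(-((ph - 80) / 15)^2)  # |v| <= 0.3 everywhere
  dyn <- makeDyn(rep(1, 101), fascicle, exp(-((ph - 25) / 12)^2))
  # threshold above all speeds -> identically zero
  expect_true(all(curveValues(dbProfile(dyn, threshold = 0.31)) == 0))
  # threshold 0 -> proportional to the direct net rate of the velocity trace
  cfg <- defaultControllerConfig("walk")
  db0 <- dbProfile(dyn, cfg, threshold = 0)
  direct <- netAtpRate(fascicle, 1, cfg@composition, cfg@corrections,
                       list(slow = cfg@slowFiber, fast = cfg@fastFiber))
  expect_equal(curveValues(db0), direct)
})

test_that("calibrate peak-matches exactly and records the scale factor", {
  p <- randomProfile(101L)
  mx <- max(curveValues(p))
  same <- calibrate(p, mx)
  expect_equal(scaleFactor(same), 1)
  expect_equal(curveValues(same), curveValues(p))

  p2 <- calibrate(p, 0.5)
  expect_equal(max(curveValues(p2)), 0.5, tolerance = 1e-15)
  expect_equal(scaleFactor(p2), 0.5 / mx)

  zero <- TorqueProfile(GaitCurve(c(0, 100), c(0, 0), "stance",
                                  "assistive_torque"), controller = "DB")
  expect_error(calibrate(zero, 0.5), "all-zero")
  expect_error(calibrate(p, -1), "positive")
})

test_that("key-point timings are invariant under calibration", {
  set.seed(33)
  for (i in 1:10) {
    p <- randomProfile(101L)
    kp <- keyPoints(p, 0.039)
    k <- runif(1, 0.01, 50)
    kp2 <- keyPoints(calibrate(p, k * max(curveValues(p))), 0.039)
    expect_equal(onsetPercent(kp2), onsetPercent(kp))
    expect_equal(peakPercent(kp2), peakPercent(kp))
    expect_equal(offsetPercent(kp2), offsetPercent(kp))
  }
})
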