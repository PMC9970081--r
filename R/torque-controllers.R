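## The two energetics-based torque controllers. FS multiplies the
## muscle-tendon-unit force by the net ATP hydrolysis rate (with a 1/3.6
## eccentric force discount on lengthening samples); DB uses the net rate
## alone, computed with a fascicle-speed deadband set at the instant of peak
## tendon lengthening velocity. Both are uncalibrated (scale factor 1) until
## peak-matched against a reference profile with calibrate().

#' Convert joint torque to muscle-tendon-unit force
#'
#' Pointwise division by a constant Achilles-tendon moment arm (default
#' 4.2 cm). The sign is preserved: negative samples flag
#' dorsiflexion-direction torque and feed the `F < 0` branch of the
#' controllers. With body-mass-normalized torque (Nm/kg) the result is a
#' body-mass-normalized force (N/kg).
#'
#' @param x a [GaitCurve-class] of quantity `"joint_torque"`.
#' @param momentArm moment arm in meters, positive.
#' @return A numeric vector of forces aligned with `phasePoints(x)`.
#' @export
setMethod("mtuForce", "GaitCurve", function(x, momentArm = 0.042) {
  if (x@quantity != "joint_torque")
    stop("mtuForce expects a joint_torque curve")
  if (length(momentArm) != 1L || !is.finite(momentArm) || momentArm <= 0)
    stop("momentArm must be a single positive number (configuration error)")
  x@values / momentArm
})

#' Fascicle-speed deadband threshold from tendon dynamics
#'
#' Locates the global maximum of the tendon lengthening velocity (earliest
#' sample on ties) and returns the absolute fascicle velocity at that instant
#' together with the phase where it occurs. This speed is the deadband
#' threshold of the DB controller: below it the fascicles are assumed to be
#' tensioning the tendon, and assisting would interfere with elastic energy
#' storage.
#'
#' If the tendon never lengthens (all velocities nonpositive) the
#' least-negative sample is used and a warning is raised.
#'
#' @param x an [MtuDynamics-class].
#' @return A [DeadbandResult-class].
#' @export
setMethod("deadbandSpeed", "MtuDynamics", function(x) {
  tv <- x@tendonVelocity@values
  if (all(tv <= 0))
    warning("tendon velocity never positive; deadband from least-negative sample")
  i <- which.max(tv)  # earliest index on exact ties
  new("DeadbandResult",
      thresholdSpeed = abs(x@fascicleVelocity@values[i]),
      tendonPeakPhase = x@tendonVelocity@phase[i])
})

.assistiveProfile <- function(dynamics, values, controller) {
  if (any(values < -1e-12))
    stop("internal error: controller produced a negative assistive torque")
  curve <- initialize(dynamics@torque, values = pmax(values, 0),
                      quantity = "assistive_torque",
                      units = .quantityUnits("assistive_torque"))
  TorqueProfile(curve, scaleFactor = 1, controller = controller)
}

#' Force-scaled (FS) assistive torque profile
#'
#' Pointwise product of the muscle-tendon-unit force and the net ATP
#' hydrolysis rate of the fascicles:
#' \itemize{
#'   \item 0 where the force is negative,
#'   \item `F * AsNet(vCe)` on shortening samples (`vCe <= 0`),
#'   \item `(1/3.6) * F * AsNet(vCe)` on lengthening samples (eccentric force
#'     discount, on top of the 1/2.7 velocity discount already inside
#'     `AsNet`).
#' }
#' Assistance therefore mimics the human torque, concentrated where the
#' muscle spends chemical energy. The output is uncalibrated (scale factor 1,
#' arbitrary units until [calibrate()] peak-matches it).
#'
#' @param x an [MtuDynamics-class].
#' @param config a [ControllerConfig-class].
#' @param ... unused.
#' @return A [TorqueProfile-class] with `controller = "FS"`.
#' @export
setMethod("fsProfile", "MtuDynamics", function(x, config = ControllerConfig(), ...) {
  stopifnot(is(config, "ControllerConfig"))
  f <- mtuForce(x@torque, config@momentArm)
  v <- x@fascicleVelocity@values
  rate <- netAtpRate(v, f, config@composition, config@corrections,
                     fibers = list(slow = config@slowFiber, fast = config@fastFiber),
                     mode = "direct")
  out <- f * rate
  out[v > 0] <- out[v > 0] * config@corrections@forceFactor
  out[f < 0] <- 0
  .assistiveProfile(x, out, "FS")
})

#' Deadbanded (DB) assistive torque profile
#'
#' The net ATP hydrolysis rate evaluated on a deadband-shifted fascicle
#' speed: speeds at or below the fascicle speed observed at peak tendon
#' lengthening velocity (see [deadbandSpeed()]) count as zero, which keeps
#' the exoskeleton quiet while the tendon is being loaded in early stance.
#' Force enters only through its sign (`F < 0` samples are zeroed); the
#' profile magnitude is independent of the torque input. Uncalibrated.
#'
#' @param x an [MtuDynamics-class].
#' @param config a [ControllerConfig-class].
#' @param threshold optional [DeadbandResult-class] or single nonnegative
#'   speed; computed from `x` when missing.
#' @param ... unused.
#' @return A [TorqueProfile-class] with `controller = "DB"`.
#' @export
setMethod("dbProfile", "MtuDynamics", function(x, config = ControllerConfig(),
                                               threshold = NULL, ...) {
  stopifnot(is(config, "ControllerConfig"))
  if (is.null(threshold)) threshold <- deadbandSpeed(x)
  th <- if (is(threshold, "DeadbandResult")) threshold@thresholdSpeed else
    as.numeric(threshold)
  f <- mtuForce(x@torque, config@momentArm)
  v <- x@fascicleVelocity@values
  out <- netAtpRate(v, f, config@composition, config@corrections,
                    fibers = list(slow = config@slowFiber, fast = config@fastFiber),
                    mode = "shifted", thresholdSpeed = th)
  .assistiveProfile(x, out, "DB")
})

#' Peak-match a torque profile to a target magnitude
#'
#' Multiplies the profile by `targetPeak / max(values)` so its maximum equals
#' `targetPeak` exactly, and records the scale factor (the controllers' C
#' constant). The same factor is reusable across speeds of one gait type: the
#' calibration anchors are 1.4 m/s for walking and 3.0 m/s for running, and
#' all other speeds of that gait reuse the anchor's factor (see
#' [applyScaleFactor()]).
#'
#' @param x a [TorqueProfile-class] with a strictly positive maximum.
#' @param targetPeak target peak torque, Nm/kg, positive.
#' @return The calibrated [TorqueProfile-class]; `scaleFactor` multiplied by
#'   the factor just applied.
#' @export
setMethod("calibrate", "TorqueProfile", function(x, targetPeak) {
  if (length(targetPeak) != 1L || !is.finite(targetPeak) || targetPeak <= 0)
    stop("targetPeak must be a single positive number")
  mx <- max(x@curve@values)
  if (mx <= 0)
    stop("cannot calibrate an all-zero profile")
  k <- targetPeak / mx
  initialize(x, curve = initialize(x@curve, values = x@curve@values * k),
             scaleFactor = x@scaleFactor * k)
})

#' Apply a previously determined scale factor
#'
#' Rescales an uncalibrated profile by a known factor (e.g. the anchor
#' speed's calibration constant applied to the other speeds of the same gait
#' type).
#'
#' @param x a [TorqueProfile-class].
#' @param factor positive scale factor.
#' @return The rescaled profile.
#' @export
applyScaleFactor <- function(x, factor) {
  stopifnot(is(x, "TorqueProfile"))
  if (length(factor) != 1L || !is.finite(factor) || factor <= 0)
    stop("factor must be a single positive number")
  initialize(x, curve = initialize(x@curve, values = x@curve@values * factor),
             scaleFactor = x@scaleFactor * factor)
}
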