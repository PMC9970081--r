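## Central S4 classes. Sign convention used throughout: velocities are
## lengthening-positive (shortening negative); plantarflexion torque positive.

.PHASE_KINDS <- c("stance", "gait")
.QUANTITIES <- c("joint_torque", "fascicle_velocity", "tendon_velocity",
                 "assistive_torque")
.GAIT_TYPES <- c("walk", "run")
.CONTROLLERS <- c("FS", "DB", "HITL", "EO")

.quantityUnits <- function(quantity) {
  switch(quantity,
         joint_torque = "Nm/kg",
         assistive_torque = "Nm/kg",
         fascicle_velocity = "l0/s",
         tendon_velocity = "l0/s",
         "")
}

#' GaitCurve: one quantity sampled over a gait-cycle phase axis
#'
#' The universal waveform carrier: a named quantity (joint torque in Nm/kg,
#' normalized fascicle or tendon velocity in resting lengths per second, or
#' assistive torque) sampled on a percent-of-stance or percent-of-gait axis.
#'
#' @slot phase numeric, strictly increasing percent values in \[0, 100\].
#' @slot values numeric samples, same length as `phase`, all finite.
#' @slot phaseKind `"stance"` or `"gait"`.
#' @slot quantity one of `"joint_torque"`, `"fascicle_velocity"`,
#'   `"tendon_velocity"`, `"assistive_torque"`.
#' @slot units unit label carried as metadata (derived from `quantity`).
#'
#' @exportClass GaitCurve
setClass("GaitCurve",
         representation(phase = "numeric", values = "numeric",
                        phaseKind = "character", quantity = "character",
                        units = "character"))

setValidity("GaitCurve", function(object) {
  msgs <- character()
  if (length(object@phase) != length(object@values))
    msgs <- c(msgs, "phase and values must have the same length")
  if (length(object@phase) < 2L)
    msgs <- c(msgs, "a curve needs at least 2 samples")
  if (!all(is.finite(object@phase)) || !all(is.finite(object@values)))
    msgs <- c(msgs, "phase and values must be finite")
  else {
    if (any(diff(object@phase) <= 0))
      msgs <- c(msgs, "phase axis must be strictly increasing")
    if (object@phase[1L] < 0 || object@phase[length(object@phase)] > 100)
      msgs <- c(msgs, "phase axis must lie within [0, 100]")
  }
  if (length(object@phaseKind) != 1L || !object@phaseKind %in% .PHASE_KINDS)
    msgs <- c(msgs, "phaseKind must be 'stance' or 'gait'")
  if (length(object@quantity) != 1L || !object@quantity %in% .QUANTITIES)
    msgs <- c(msgs, sprintf("quantity must be one of: %s",
                            paste(.QUANTITIES, collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' Construct a GaitCurve
#'
#' @param phase numeric percent-of-cycle axis, strictly increasing, within
#'   \[0, 100\].
#' @param values numeric samples aligned with `phase`.
#' @param phaseKind `"stance"` (percent of stance phase) or `"gait"` (percent
#'   of the full gait cycle).
#' @param quantity what the samples measure; controls the unit label.
#' @return A [GaitCurve-class] object.
#' @examples
#' gc <- GaitCurve(c(0, 50, 100), c(0, 1, 0), "stance", "joint_torque")
#' phasePoints(gc)
#' @export
GaitCurve <- function(phase, values,
                      phaseKind = c("stance", "gait"),
                      quantity = c("joint_torque", "fascicle_velocity",
                                   "tendon_velocity", "assistive_torque")) {
  phaseKind <- match.arg(phaseKind)
  quantity <- match.arg(quantity)
  new("GaitCurve", phase = as.numeric(phase), values = as.numeric(values),
      phaseKind = phaseKind, quantity = quantity,
      units = .quantityUnits(quantity))
}

#' MtuDynamics: aligned muscle-tendon dynamics for one speed condition
#'
#' Joint torque, normalized fascicle velocity and normalized tendon velocity
#' sampled on one shared phase axis, for a single locomotion speed.
#' Velocities arrive already normalized by the resting fascicle length (the
#' length during quiet standing), lengthening positive.
#'
#' @slot torque [GaitCurve-class], joint torque (Nm/kg, plantarflexion
#'   positive).
#' @slot fascicleVelocity [GaitCurve-class], normalized contractile-element
#'   velocity (lengthening positive).
#' @slot tendonVelocity [GaitCurve-class], normalized series-tendon velocity
#'   (lengthening positive).
#' @slot speed numeric, locomotion speed in m/s.
#' @slot gaitType `"walk"` or `"run"`.
#'
#' @exportClass MtuDynamics
setClass("MtuDynamics",
         representation(torque = "GaitCurve",
                        fascicleVelocity = "GaitCurve",
                        tendonVelocity = "GaitCurve",
                        speed = "numeric", gaitType = "character"))

setValidity("MtuDynamics", function(object) {
  msgs <- character()
  ax <- object@torque@phase
  if (!identical(ax, object@fascicleVelocity@phase) ||
      !identical(ax, object@tendonVelocity@phase))
    msgs <- c(msgs, "torque, fascicle and tendon curves must share one phase axis")
  kinds <- c(object@torque@phaseKind, object@fascicleVelocity@phaseKind,
             object@tendonVelocity@phaseKind)
  if (length(unique(kinds)) != 1L)
    msgs <- c(msgs, "all curves must share one phaseKind")
  if (object@torque@quantity != "joint_torque")
    msgs <- c(msgs, "torque slot must carry quantity 'joint_torque'")
  if (object@fascicleVelocity@quantity != "fascicle_velocity")
    msgs <- c(msgs, "fascicleVelocity slot must carry quantity 'fascicle_velocity'")
  if (object@tendonVelocity@quantity != "tendon_velocity")
    msgs <- c(msgs, "tendonVelocity slot must carry quantity 'tendon_velocity'")
  if (length(object@speed) != 1L || !is.finite(object@speed) || object@speed <= 0)
    msgs <- c(msgs, "speed must be a single positive number")
  if (length(object@gaitType) != 1L || !object@gaitType %in% .GAIT_TYPES)
    msgs <- c(msgs, "gaitType must be 'walk' or 'run'")
  if (length(msgs)) msgs else TRUE
})

## interpolate a curve onto a reference phase axis (endpoint hold outside)
.alignTo <- function(curve, phase) {
  if (identical(curve@phase, phase)) return(curve)
  v <- stats::approx(curve@phase, curve@values, xout = phase, rule = 2)$y
  initialize(curve, phase = phase, values = v)
}

#' Construct MtuDynamics
#'
#' If the three curves do not share a phase axis they are linearly
#' interpolated onto the torque curve's axis (values outside a source range
#' held at the nearest endpoint).
#'
#' @param torque,fascicleVelocity,tendonVelocity [GaitCurve-class] objects of
#'   the matching quantities, same `phaseKind`.
#' @param speed locomotion speed in m/s.
#' @param gaitType `"walk"` or `"run"`.
#' @return An [MtuDynamics-class] object.
#' @export
MtuDynamics <- function(torque, fascicleVelocity, tendonVelocity,
                        speed, gaitType = c("walk", "run")) {
  gaitType <- match.arg(gaitType)
  ax <- torque@phase
  new("MtuDynamics", torque = torque,
      fascicleVelocity = .alignTo(fascicleVelocity, ax),
      tendonVelocity = .alignTo(tendonVelocity, ax),
      speed = as.numeric(speed), gaitType = gaitType)
}

#' FiberParams: hyperbola constants of the ATP-hydrolysis-rate model
#'
#' `M` is the asymptotic ATP hydrolysis rate at infinite shortening velocity
#' and `D` is the inverse of the normalized velocity at which half of `M` is
#' reached. Rate units are arbitrary: the downstream peak-matching scale
#' factor absorbs them.
#'
#' @slot M positive asymptotic rate (arbitrary ATP-rate units).
#' @slot D positive inverse half-asymptote velocity (per normalized velocity).
#' @exportClass FiberParams
setClass("FiberParams", representation(M = "numeric", D = "numeric"))

setValidity("FiberParams", function(object) {
  if (length(object@M) != 1L || !is.finite(object@M) || object@M <= 0)
    return("M must be a single positive number")
  if (length(object@D) != 1L || !is.finite(object@D) || object@D <= 0)
    return("D must be a single positive number")
  TRUE
})

#' @param M,D see slot descriptions.
#' @return A [FiberParams-class] object.
#' @rdname FiberParams-class
#' @export
FiberParams <- function(M, D) new("FiberParams", M = as.numeric(M), D = as.numeric(D))

#' FiberComposition: slow/fast fiber mixing fractions
#'
#' Fractions of the muscle cross-section made of slow-twitch (type I) and
#' fast-twitch (type IIA) fibers; they must sum to one. The soleus default is
#' 0.8 slow / 0.2 fast.
#'
#' @slot rSlow,rFast fractions in \[0, 1\] summing to 1.
#' @exportClass FiberComposition
setClass("FiberComposition", representation(rSlow = "numeric", rFast = "numeric"))

setValidity("FiberComposition", function(object) {
  msgs <- character()
  for (nm in c("rSlow", "rFast")) {
    v <- slot(object, nm)
    if (length(v) != 1L || !is.finite(v) || v < 0 || v > 1)
      msgs <- c(msgs, sprintf("%s must be a single value in [0, 1]", nm))
  }
  if (!length(msgs) && abs(object@rSlow + object@rFast - 1) > 1e-9)
    msgs <- c(msgs, "rSlow + rFast must equal 1 (tolerance 1e-9)")
  if (length(msgs)) msgs else TRUE
})

#' @param rSlow slow-twitch fraction; `rFast` defaults to its complement.
#' @param rFast fast-twitch fraction.
#' @return A [FiberComposition-class] object.
#' @rdname FiberComposition-class
#' @export
FiberComposition <- function(rSlow = 0.8, rFast = 1 - rSlow)
  new("FiberComposition", rSlow = as.numeric(rSlow), rFast = as.numeric(rFast))

#' EccentricCorrections: metabolic discounts for lengthening contractions
#'
#' Eccentric (lengthening) contractions consume less ATP per unit velocity
#' and force than concentric ones; fixed correction factors of 1/2.7
#' (velocity) and 1/3.6 (force) are applied on the lengthening branch. Both
#' were measured at the knee-joint level and are kept configurable.
#'
#' @slot velocityFactor factor multiplying the mixed ATP rate when the
#'   fascicle lengthens (default 1/2.7).
#' @slot forceFactor factor multiplying the force term of the force-scaled
#'   controller when the fascicle lengthens (default 1/3.6).
#' @exportClass EccentricCorrections
setClass("EccentricCorrections",
         representation(velocityFactor = "numeric", forceFactor = "numeric"))

setValidity("EccentricCorrections", function(object) {
  for (nm in c("velocityFactor", "forceFactor")) {
    v <- slot(object, nm)
    if (length(v) != 1L || !is.finite(v) || v <= 0 || v > 1)
      return(sprintf("%s must be a single value in (0, 1]", nm))
  }
  TRUE
})

#' @param velocityFactor,forceFactor see slot descriptions.
#' @return An [EccentricCorrections-class] object.
#' @rdname EccentricCorrections-class
#' @export
EccentricCorrections <- function(velocityFactor = 1 / 2.7, forceFactor = 1 / 3.6)
  new("EccentricCorrections", velocityFactor = as.numeric(velocityFactor),
      forceFactor = as.numeric(forceFactor))

#' ControllerConfig: all parameters of the torque controllers
#'
#' @slot momentArm constant Achilles-tendon moment arm in meters (default
#'   0.042 m, the mean over 20--60 percent of the walking gait cycle).
#' @slot composition [FiberComposition-class].
#' @slot corrections [EccentricCorrections-class].
#' @slot slowFiber,fastFiber [FiberParams-class] for type I / type IIA fibers.
#' @slot onsetFraction onset/offset threshold as a fraction of peak torque
#'   (0.039 for walking, 0.088 for running).
#' @exportClass ControllerConfig
setClass("ControllerConfig",
         representation(momentArm = "numeric",
                        composition = "FiberComposition",
                        corrections = "EccentricCorrections",
                        slowFiber = "FiberParams", fastFiber = "FiberParams",
                        onsetFraction = "numeric"))

setValidity("ControllerConfig", function(object) {
  msgs <- character()
  if (length(object@momentArm) != 1L || !is.finite(object@momentArm) ||
      object@momentArm <= 0)
    msgs <- c(msgs, "momentArm must be a single positive number (meters)")
  if (length(object@onsetFraction) != 1L || !is.finite(object@onsetFraction) ||
      object@onsetFraction <= 0 || object@onsetFraction >= 1)
    msgs <- c(msgs, "onsetFraction must lie in (0, 1)")
  if (length(msgs)) msgs else TRUE
})

#' @param momentArm,composition,corrections,slowFiber,fastFiber,onsetFraction
#'   see slot descriptions.
#' @return A [ControllerConfig-class] object.
#' @rdname ControllerConfig-class
#' @export
ControllerConfig <- function(momentArm = 0.042,
                             composition = FiberComposition(),
                             corrections = EccentricCorrections(),
                             slowFiber = FiberParams(1, 4),
                             fastFiber = FiberParams(3, 1.5),
                             onsetFraction = 0.039) {
  new("ControllerConfig", momentArm = as.numeric(momentArm),
      composition = composition, corrections = corrections,
      slowFiber = slowFiber, fastFiber = fastFiber,
      onsetFraction = as.numeric(onsetFraction))
}

#' TorqueProfile: a generated or reference assistive-torque waveform
#'
#' @slot curve [GaitCurve-class] of quantity `"assistive_torque"`, all values
#'   nonnegative.
#' @slot scaleFactor positive peak-matching scale factor already applied to
#'   the values (1 when uncalibrated).
#' @slot controller `"FS"`, `"DB"`, `"HITL"` or `"EO"`.
#' @exportClass TorqueProfile
setClass("TorqueProfile",
         representation(curve = "GaitCurve", scaleFactor = "numeric",
                        controller = "character"))

setValidity("TorqueProfile", function(object) {
  msgs <- character()
  if (object@curve@quantity != "assistive_torque")
    msgs <- c(msgs, "curve must carry quantity 'assistive_torque'")
  if (any(object@curve@values < 0))
    msgs <- c(msgs, "assistive torque values must be nonnegative")
  if (length(object@scaleFactor) != 1L || !is.finite(object@scaleFactor) ||
      object@scaleFactor <= 0)
    msgs <- c(msgs, "scaleFactor must be a single positive number")
  if (length(object@controller) != 1L || !object@controller %in% .CONTROLLERS)
    msgs <- c(msgs, sprintf("controller must be one of: %s",
                            paste(.CONTROLLERS, collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' @param curve,scaleFactor,controller see slot descriptions.
#' @return A [TorqueProfile-class] object.
#' @rdname TorqueProfile-class
#' @export
TorqueProfile <- function(curve, scaleFactor = 1,
                          controller = c("FS", "DB", "HITL", "EO")) {
  controller <- match.arg(controller)
  new("TorqueProfile", curve = curve, scaleFactor = as.numeric(scaleFactor),
      controller = controller)
}

#' DeadbandResult: the fascicle-speed deadband threshold
#'
#' The absolute fascicle velocity observed at the instant of peak tendon
#' lengthening velocity, and the phase where that peak occurs.
#'
#' @slot thresholdSpeed nonnegative normalized fascicle speed.
#' @slot tendonPeakPhase percent of cycle where tendon velocity peaks.
#' @exportClass DeadbandResult
setClass("DeadbandResult",
         representation(thresholdSpeed = "numeric", tendonPeakPhase = "numeric"))

setValidity("DeadbandResult", function(object) {
  if (length(object@thresholdSpeed) != 1L || !is.finite(object@thresholdSpeed) ||
      object@thresholdSpeed < 0)
    return("thresholdSpeed must be a single nonnegative number")
  if (length(object@tendonPeakPhase) != 1L || !is.finite(object@tendonPeakPhase))
    return("tendonPeakPhase must be a single finite number")
  TRUE
})

#' HitlParams: key parameters of a HITL-style reference torque profile
#'
#' Onset/peak/offset timings (percent of cycle), peak torque, and the small
#' pre-onset tensioning torque reached by a linear ramp from the start of the
#' cycle.
#'
#' @slot onsetPercent,peakPercent,offsetPercent percent of cycle with
#'   `0 <= onset < peak < offset <= 100`.
#' @slot peakTorque peak assistive torque (Nm/kg).
#' @slot onsetTorque cable-tensioning torque at onset, in \[0, peakTorque).
#' @exportClass HitlParams
setClass("HitlParams",
         representation(onsetPercent = "numeric", peakPercent = "numeric",
                        offsetPercent = "numeric", peakTorque = "numeric",
                        onsetTorque = "numeric"))

setValidity("HitlParams", function(object) {
  v <- c(object@onsetPercent, object@peakPercent, object@offsetPercent,
         object@peakTorque, object@onsetTorque)
  if (length(v) != 5L || !all(is.finite(v)))
    return("all five parameters must be single finite numbers")
  if (!(0 <= object@onsetPercent && object@onsetPercent < object@peakPercent &&
        object@peakPercent < object@offsetPercent && object@offsetPercent <= 100))
    return("need 0 <= onset < peak < offset <= 100")
  if (!(0 <= object@onsetTorque && object@onsetTorque < object@peakTorque))
    return("need 0 <= onsetTorque < peakTorque")
  TRUE
})

#' @param onsetPercent,peakPercent,offsetPercent,peakTorque,onsetTorque see
#'   slot descriptions.
#' @return A [HitlParams-class] object.
#' @rdname HitlParams-class
#' @export
HitlParams <- function(onsetPercent, peakPercent, offsetPercent,
                       peakTorque, onsetTorque = 0) {
  new("HitlParams", onsetPercent = as.numeric(onsetPercent),
      peakPercent = as.numeric(peakPercent),
      offsetPercent = as.numeric(offsetPercent),
      peakTorque = as.numeric(peakTorque),
      onsetTorque = as.numeric(onsetTorque))
}

#' HitlEnvelope: mean reference profile with across-subject min/max range
#'
#' @slot mean [TorqueProfile-class] built from element-wise mean parameters.
#' @slot lower,upper [GaitCurve-class] pointwise min/max over the per-subject
#'   curves.
#' @exportClass HitlEnvelope
setClass("HitlEnvelope",
         representation(mean = "TorqueProfile", lower = "GaitCurve",
                        upper = "GaitCurve"))

setValidity("HitlEnvelope", function(object) {
  m <- object@mean@curve
  if (!identical(m@phase, object@lower@phase) ||
      !identical(m@phase, object@upper@phase))
    return("mean, lower and upper must share one phase axis")
  eps <- 1e-9
  if (any(object@lower@values > m@values + eps) ||
      any(m@values > object@upper@values + eps))
    return("need lower <= mean <= upper pointwise")
  TRUE
})

#' KeyPoints: onset/peak/offset summary of a torque profile
#'
#' @slot onsetPercent,peakPercent,offsetPercent timings, percent of cycle.
#' @slot peakValue torque at the peak (Nm/kg).
#' @exportClass KeyPoints
setClass("KeyPoints",
         representation(onsetPercent = "numeric", peakPercent = "numeric",
                        offsetPercent = "numeric", peakValue = "numeric"))

setValidity("KeyPoints", function(object) {
  v <- c(object@onsetPercent, object@peakPercent, object@offsetPercent,
         object@peakValue)
  if (!all(is.finite(v))) return("all key-point fields must be finite")
  if (!(object@onsetPercent <= object@peakPercent &&
        object@peakPercent <= object@offsetPercent))
    return("need onset <= peak <= offset")
  if (object@peakValue <= 0) return("peakValue must be positive")
  TRUE
})

#' SimilarityReport: cosine similarity and discrete Frechet distance
#'
#' @slot cosineSimilarity in \[0, 1\] for nonnegative profiles (1 = identical
#'   direction).
#' @slot frechetDistance nonnegative; mixed-axis Euclidean distance over
#'   (percent phase, Nm/kg torque) points.
#' @slot nPoints number of grid points compared.
#' @exportClass SimilarityReport
setClass("SimilarityReport",
         representation(cosineSimilarity = "numeric",
                        frechetDistance = "numeric", nPoints = "integer"))

## ---- show methods ---------------------------------------------------------

setMethod("show", "GaitCurve", function(object) {
  cat(sprintf("GaitCurve: %s [%s], %d samples on %.1f-%.1f%% %s\n",
              object@quantity, object@units, length(object@phase),
              object@phase[1L], object@phase[length(object@phase)],
              object@phaseKind))
  cat(sprintf("  range of values: [%.4g, %.4g]\n",
              min(object@values), max(object@values)))
})

setMethod("show", "MtuDynamics", function(object) {
  cat(sprintf("MtuDynamics: %s at %.2f m/s, %d samples (%% %s)\n",
              object@gaitType, object@speed, length(object@torque@phase),
              object@torque@phaseKind))
  cat(sprintf("  peak torque %.3f Nm/kg; fascicle velocity in [%.3f, %.3f] l0/s\n",
              max(object@torque@values),
              min(object@fascicleVelocity@values),
              max(object@fascicleVelocity@values)))
})

setMethod("show", "TorqueProfile", function(object) {
  cat(sprintf("TorqueProfile (%s): peak %.4g Nm/kg at %.1f%% %s, scale factor %.4g\n",
              object@controller, max(object@curve@values),
              object@curve@phase[which.max(object@curve@values)],
              object@curve@phaseKind, object@scaleFactor))
})

setMethod("show", "KeyPoints", function(object) {
  cat(sprintf("KeyPoints: onset %.1f%%, peak %.1f%% (%.3f Nm/kg), offset %.1f%%\n",
              object@onsetPercent, object@peakPercent, object@peakValue,
              object@offsetPercent))
})

setMethod("show", "DeadbandResult", function(object) {
  cat(sprintf("DeadbandResult: threshold speed %.4g l0/s at %.1f%% (tendon peak)\n",
              object@thresholdSpeed, object@tendonPeakPhase))
})

setMethod("show", "SimilarityReport", function(object) {
  cat(sprintf("SimilarityReport (%d points): cosine similarity %.3f, Frechet distance %.3f\n",
              object@nPoints, object@cosineSimilarity, object@frechetDistance))
})

setMethod("show", "HitlParams", function(object) {
  cat(sprintf("HitlParams: onset %.1f%%, peak %.1f%% (%.3f Nm/kg), offset %.1f%%, onset torque %.3f\n",
              object@onsetPercent, object@peakPercent, object@peakTorque,
              object@offsetPercent, object@onsetTorque))
})
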