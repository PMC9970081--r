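## Generics and simple accessors.

#' @name soleusExo-generics
#' @title Generics for gait-curve and torque-profile operations
#' @param object,x an object of the relevant class
#' @param ... passed to methods
#' @keywords internal
NULL

#' @rdname soleusExo-generics
#' @export
setGeneric("phasePoints", function(x) standardGeneric("phasePoints"))

#' @rdname soleusExo-generics
#' @export
setGeneric("curveValues", function(x) standardGeneric("curveValues"))

#' @rdname soleusExo-generics
#' @export
setGeneric("phaseKind", function(x) standardGeneric("phaseKind"))

#' @rdname soleusExo-generics
#' @export
setGeneric("resample", function(x, nPoints = 101L, ...) standardGeneric("resample"))

#' @rdname soleusExo-generics
#' @export
setGeneric("stanceToGait", function(x, toeOffPercent = 62.7)
  standardGeneric("stanceToGait"))

#' @rdname soleusExo-generics
#' @export
setGeneric("gaitToStance", function(x, toeOffPercent = 62.7)
  standardGeneric("gaitToStance"))

#' @rdname soleusExo-generics
#' @export
setGeneric("mtuForce", function(x, momentArm = 0.042) standardGeneric("mtuForce"))

#' @rdname soleusExo-generics
#' @export
setGeneric("deadbandSpeed", function(x) standardGeneric("deadbandSpeed"))

#' @rdname soleusExo-generics
#' @export
setGeneric("fsProfile", function(x, config = ControllerConfig(), ...)
  standardGeneric("fsProfile"))

#' @rdname soleusExo-generics
#' @export
setGeneric("dbProfile", function(x, config = ControllerConfig(), ...)
  standardGeneric("dbProfile"))

#' @rdname soleusExo-generics
#' @export
setGeneric("calibrate", function(x, targetPeak) standardGeneric("calibrate"))

#' @rdname soleusExo-generics
#' @export
setGeneric("keyPoints", function(x, onsetFraction = 0.039)
  standardGeneric("keyPoints"))

#' @rdname soleusExo-generics
#' @export
setGeneric("cosineSimilarity", function(x, y) standardGeneric("cosineSimilarity"))

#' @rdname soleusExo-generics
#' @export
setGeneric("frechetDistance", function(x, y, ...) standardGeneric("frechetDistance"))

## ---- accessors ------------------------------------------------------------

#' @rdname soleusExo-generics
#' @export
setMethod("phasePoints", "GaitCurve", function(x) x@phase)

#' @rdname soleusExo-generics
#' @export
setMethod("curveValues", "GaitCurve", function(x) x@values)

#' @rdname soleusExo-generics
#' @export
setMethod("phaseKind", "GaitCurve", function(x) x@phaseKind)

#' @rdname soleusExo-generics
#' @export
setMethod("phasePoints", "TorqueProfile", function(x) x@curve@phase)

#' @rdname soleusExo-generics
#' @export
setMethod("curveValues", "TorqueProfile", function(x) x@curve@values)

#' @rdname soleusExo-generics
#' @export
setMethod("phaseKind", "TorqueProfile", function(x) x@curve@phaseKind)

#' Accessors for slots of the domain classes
#'
#' `torqueCurve()`, `fascicleVelocity()`, `tendonVelocity()` return the three
#' component curves of an [MtuDynamics-class]; `gaitSpeed()` and `gaitType()`
#' its condition metadata. `profileCurve()`, `scaleFactor()` and
#' `controllerType()` access a [TorqueProfile-class]; `thresholdSpeed()` and
#' `tendonPeakPhase()` a [DeadbandResult-class].
#'
#' @param x the object.
#' @return The slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
torqueCurve <- function(x) x@torque

#' @rdname accessors
#' @export
fascicleVelocity <- function(x) x@fascicleVelocity

#' @rdname accessors
#' @export
tendonVelocity <- function(x) x@tendonVelocity

#' @rdname accessors
#' @export
gaitSpeed <- function(x) x@speed

#' @rdname accessors
#' @export
gaitType <- function(x) x@gaitType

#' @rdname accessors
#' @export
profileCurve <- function(x) x@curve

#' @rdname accessors
#' @export
scaleFactor <- function(x) x@scaleFactor

#' @rdname accessors
#' @export
controllerType <- function(x) x@controller

#' @rdname accessors
#' @export
thresholdSpeed <- function(x) x@thresholdSpeed

#' @rdname accessors
#' @export
tendonPeakPhase <- function(x) x@tendonPeakPhase

#' @rdname accessors
#' @export
onsetPercent <- function(x) x@onsetPercent

#' @rdname accessors
#' @export
peakPercent <- function(x) x@peakPercent

#' @rdname accessors
#' @export
offsetPercent <- function(x) x@offsetPercent

#' @rdname accessors
#' @export
peakValue <- function(x) x@peakValue
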