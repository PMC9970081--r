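## Reconstruction of HITL-style reference torque profiles from their key
## parameters (onset/peak/offset timing, peak torque, pre-onset tensioning
## torque), across-subject min/max envelopes, and speed-interpolated
## "estimated optimum" (EO) parameter sets.

## closed-form evaluator: linear ramp 0 -> onsetTorque over [0, onset], then
## monotone cubic (smoothstep, zero slope at both segment ends) up to
## peakTorque at peak, down to 0 at offset, 0 afterwards. The zero-slope rise
## and fall guarantee no overshoot, so max == peakTorque at peak exactly.
.smoothstep <- function(t) t * t * (3 - 2 * t)

.hitlEval <- function(params, phase) {
  on <- params@onsetPercent; pk <- params@peakPercent
  off <- params@offsetPercent
  t0 <- params@onsetTorque; tp <- params@peakTorque
  out <- numeric(length(phase))
  ramp <- phase < on
  if (on > 0) out[ramp] <- t0 * phase[ramp] / on
  rise <- phase >= on & phase <= pk
  out[rise] <- t0 + (tp - t0) * .smoothstep((phase[rise] - on) / (pk - on))
  fall <- phase > pk & phase <= off
  out[fall] <- tp * (1 - .smoothstep((phase[fall] - pk) / (off - pk)))
  out
}

#' Reconstruct a HITL-style reference torque profile
#'
#' Builds the parameterized torque waveform used by human-in-the-loop
#' optimization studies: zero torque ramps linearly to a small
#' cable-tensioning torque at onset, rises smoothly to the peak, falls
#' smoothly back to zero at offset, and stays zero afterwards. The rise and
#' fall are monotone cubic segments with zero slope at the peak and at
#' offset, so the curve is continuous, never overshoots, and its maximum
#' equals `peakTorque` exactly. The exact spline family of the original
#' studies is not published; this shape is a reconstruction choice.
#'
#' The three knot phases are inserted into the output grid (set
#' `includeKnots = FALSE` for a strictly uniform grid).
#'
#' @param params a [HitlParams-class].
#' @param grid phase axis (percent), default 0--100 at 1% increments.
#' @param phaseKind axis kind of the output (`"gait"` for the walking
#'   references, `"stance"` for running).
#' @param controller label for the output profile (`"HITL"` or `"EO"`).
#' @param includeKnots insert onset/peak/offset phases into the grid.
#' @return A [TorqueProfile-class].
#' @examples
#' p <- HitlParams(20, 50, 62, peakTorque = 1, onsetTorque = 0.039)
#' max(curveValues(hitlCurve(p)))  # exactly 1
#' @export
hitlCurve <- function(params, grid = seq(0, 100, by = 1),
                      phaseKind = c("gait", "stance"),
                      controller = c("HITL", "EO"), includeKnots = TRUE) {
  stopifnot(is(params, "HitlParams"))
  phaseKind <- match.arg(phaseKind)
  controller <- match.arg(controller)
  validObject(params)
  if (includeKnots)
    grid <- sort(unique(c(grid, params@onsetPercent, params@peakPercent,
                          params@offsetPercent)))
  curve <- GaitCurve(grid, .hitlEval(params, grid), phaseKind = phaseKind,
                     quantity = "assistive_torque")
  TorqueProfile(curve, scaleFactor = 1, controller = controller)
}

#' Across-subject envelope of HITL reference profiles
#'
#' The central profile is built from the element-wise mean of the subjects'
#' parameters; the band is the pointwise minimum and maximum over the
#' per-subject curves (the mean curve is included in the extrema so the band
#' always contains it, which matters when subjects' peak timings straddle the
#' mean).
#'
#' @param subjectParams nonempty list of [HitlParams-class], one per subject.
#' @param grid shared phase axis (percent).
#' @param phaseKind axis kind (see [hitlCurve()]).
#' @return A [HitlEnvelope-class].
#' @export
hitlEnvelope <- function(subjectParams, grid = seq(0, 100, by = 1),
                         phaseKind = c("gait", "stance")) {
  phaseKind <- match.arg(phaseKind)
  if (!is.list(subjectParams) || length(subjectParams) == 0L)
    stop("subjectParams must be a nonempty list of HitlParams")
  stopifnot(all(vapply(subjectParams, is, logical(1), "HitlParams")))
  meanParams <- HitlParams(
    mean(vapply(subjectParams, onsetPercent, numeric(1))),
    mean(vapply(subjectParams, peakPercent, numeric(1))),
    mean(vapply(subjectParams, offsetPercent, numeric(1))),
    mean(vapply(subjectParams, function(p) p@peakTorque, numeric(1))),
    mean(vapply(subjectParams, function(p) p@onsetTorque, numeric(1))))
  ## one shared axis: the grid plus the mean-parameter knots
  ax <- sort(unique(c(grid, meanParams@onsetPercent, meanParams@peakPercent,
                      meanParams@offsetPercent)))
  meanProfile <- hitlCurve(meanParams, ax, phaseKind, includeKnots = FALSE)
  mat <- vapply(subjectParams, .hitlEval, numeric(length(ax)), phase = ax)
  mat <- cbind(mat, meanProfile@curve@values)
  lower <- GaitCurve(ax, apply(mat, 1L, min), phaseKind, "assistive_torque")
  upper <- GaitCurve(ax, apply(mat, 1L, max), phaseKind, "assistive_torque")
  new("HitlEnvelope", mean = meanProfile, lower = lower, upper = upper)
}

#' Speed-interpolated (estimated optimum) reference parameters
#'
#' Linearly interpolates each of the five profile parameters independently in
#' speed between anchor parameter sets, reproducing anchors exactly at their
#' own speeds. Queries outside the anchor range are refused by default;
#' `extrapolate = TRUE` extends linearly from the nearest two anchors with a
#' warning (an extension beyond what the cited interpolation scheme did).
#'
#' @param speed query speed, m/s.
#' @param anchors list of `list(speed = , params = HitlParams)` with at least
#'   two distinct speeds.
#' @param extrapolate allow linear extrapolation outside the anchor range.
#' @return A [HitlParams-class] at the query speed.
#' @examples
#' a <- list(list(speed = 0.75, params = HitlParams(20, 50, 62, 0.4)),
#'           list(speed = 1.25, params = HitlParams(22, 52, 63, 0.6)))
#' eoParams(1.0, a)  # parameter-wise midpoint
#' @export
eoParams <- function(speed, anchors, extrapolate = FALSE) {
  if (!is.list(anchors) || length(anchors) < 2L)
    stop("need at least two anchors")
  sp <- vapply(anchors, function(a) as.numeric(a$speed), numeric(1))
  if (anyDuplicated(sp))
    stop("duplicate anchor speeds (parameter error)")
  ord <- order(sp)
  sp <- sp[ord]
  anchors <- anchors[ord]
  if (speed < sp[1L] || speed > sp[length(sp)]) {
    if (!extrapolate)
      stop(sprintf("speed %.3g outside anchor range [%.3g, %.3g]; set extrapolate = TRUE",
                   speed, sp[1L], sp[length(sp)]))
    warning("extrapolating reference parameters beyond the anchor speed range")
  }
  pick <- function(field) vapply(anchors, function(a) slot(a$params, field),
                                 numeric(1))
  interp1 <- function(y) {
    if (speed <= sp[1L]) i <- 1L
    else if (speed >= sp[length(sp)]) i <- length(sp) - 1L
    else i <- findInterval(speed, sp)
    y[i] + (y[i + 1L] - y[i]) * (speed - sp[i]) / (sp[i + 1L] - sp[i])
  }
  HitlParams(interp1(pick("onsetPercent")), interp1(pick("peakPercent")),
             interp1(pick("offsetPercent")), interp1(pick("peakTorque")),
             interp1(pick("onsetTorque")))
}
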