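## Waveform comparison machinery: onset/peak/offset key points via a
## relative-threshold rule, cosine similarity of the profiles as vectors, and
## the discrete Frechet distance over (phase, torque) points.

#' Onset/peak/offset key points of a torque profile
#'
#' The threshold is a fixed fraction of the profile's own peak (the average
#' HITL onset torque as a percent of peak: 3.9% for walking, 8.8% for
#' running). The peak is the global maximum (earliest sample on ties); onset
#' is the last up-crossing of the threshold at or before the peak and offset
#' the first down-crossing after it, both located by linear interpolation
#' between samples rather than snapped to grid bins. Because the threshold is
#' relative, all three timings are invariant under positive rescaling of the
#' profile, so calibration never moves them. With a multi-lobed profile the
#' "last up-crossing before the peak" rule anchors onset to the main lobe: a
#' separate early bump cannot masquerade as onset.
#'
#' @param x a [TorqueProfile-class] (or [GaitCurve-class]) with a positive
#'   maximum.
#' @param onsetFraction threshold as a fraction of the peak, in (0, 1).
#' @return A [KeyPoints-class].
#' @examples
#' tri <- GaitCurve(c(0, 50, 100), c(0, 1, 0), "gait", "assistive_torque")
#' keyPoints(TorqueProfile(tri, controller = "FS"), 0.039) # onset 1.95, offset 98.05
#' @rdname keyPoints
#' @export
setMethod("keyPoints", "GaitCurve", function(x, onsetFraction = 0.039) {
  if (length(onsetFraction) != 1L || !is.finite(onsetFraction) ||
      onsetFraction <= 0 || onsetFraction >= 1)
    stop("onsetFraction must lie in (0, 1)")
  v <- x@values
  p <- x@phase
  mx <- max(v)
  if (mx <= 0)
    stop("key points undefined: profile has no positive maximum")
  thr <- onsetFraction * mx
  peakI <- which.max(v)
  cross <- function(i) # phase where the segment [i, i+1] meets the threshold
    p[i] + (thr - v[i]) / (v[i + 1L] - v[i]) * (p[i + 1L] - p[i])
  onset <- p[1L]
  if (peakI > 1L) {
    up <- which(v[seq_len(peakI - 1L)] < thr & v[2:peakI] >= thr)
    if (length(up)) onset <- cross(up[length(up)])
  }
  offset <- p[length(p)]
  if (peakI < length(v)) {
    dn <- which(v[peakI:(length(v) - 1L)] >= thr & v[(peakI + 1L):length(v)] < thr)
    if (length(dn)) offset <- cross(dn[1L] + peakI - 1L)
  }
  new("KeyPoints", onsetPercent = onset, peakPercent = p[peakI],
      offsetPercent = offset, peakValue = mx)
})

#' @rdname keyPoints
#' @export
setMethod("keyPoints", "TorqueProfile", function(x, onsetFraction = 0.039)
  keyPoints(x@curve, onsetFraction))

.checkSharedGrid <- function(a, b) {
  if (a@phaseKind != b@phaseKind)
    stop("cannot compare curves on different phase kinds (stance vs gait)")
  if (length(a@phase) != length(b@phase) ||
      max(abs(a@phase - b@phase)) > 1e-9)
    stop("curves must share one phase grid; resample() them first")
}

#' Cosine similarity of two profiles as vectors
#'
#' The sampled profiles (conventionally resampled to 101 stance-phase points)
#' are treated as vectors and the cosine of the angle between them returned:
#' 1 means identical direction, 0 orthogonal (disjoint support). For
#' nonnegative profiles the value lies in \[0, 1\]. Invariant under positive
#' rescaling of either profile.
#'
#' @param x,y [TorqueProfile-class] (or [GaitCurve-class]) objects on one
#'   shared phase grid, neither all-zero.
#' @return A single number in \[-1, 1\].
#' @rdname cosineSimilarity
#' @export
setMethod("cosineSimilarity", signature("GaitCurve", "GaitCurve"), function(x, y) {
  .checkSharedGrid(x, y)
  na <- sqrt(sum(x@values^2))
  nb <- sqrt(sum(y@values^2))
  if (na == 0 || nb == 0)
    stop("cosine similarity undefined for an all-zero profile")
  sum(x@values * y@values) / (na * nb)
})

#' @rdname cosineSimilarity
#' @export
setMethod("cosineSimilarity", signature("TorqueProfile", "TorqueProfile"),
          function(x, y) cosineSimilarity(x@curve, y@curve))

## discrete Frechet distance by the standard dynamic-programming recurrence
## over the coupling lattice; points are (phase, value) pairs, Euclidean
## metric, optional per-axis weights.
.frechetDP <- function(p1, v1, p2, v2, w = c(1, 1)) {
  n <- length(p1); m <- length(p2)
  dx <- outer(p1 * w[1], p2 * w[1], "-")
  dy <- outer(v1 * w[2], v2 * w[2], "-")
  d <- sqrt(dx * dx + dy * dy)
  ca <- matrix(0, n, m)
  ca[1L, 1L] <- d[1L, 1L]
  for (i in 2:n) ca[i, 1L] <- max(ca[i - 1L, 1L], d[i, 1L])
  for (j in 2:m) ca[1L, j] <- max(ca[1L, j - 1L], d[1L, j])
  for (i in 2:n)
    for (j in 2:m)
      ca[i, j] <- max(d[i, j],
                      min(ca[i - 1L, j], ca[i, j - 1L], ca[i - 1L, j - 1L]))
  ca[n, m]
}

#' Discrete Frechet distance between two sampled profiles
#'
#' Minimum over monotone couplings of the maximum pointwise distance between
#' the two curves, computed by the standard dynamic-programming recurrence.
#' Points are 2-D: phase on its 0--100 percent scale and torque in Nm/kg,
#' with the Euclidean point metric and no axis normalization (an axis-weight
#' pair is exposed, default `c(1, 1)`). Symmetric, zero iff the curves are
#' identical, and unlike cosine similarity *not* invariant under rescaling of
#' a profile.
#'
#' @param x,y [TorqueProfile-class] (or [GaitCurve-class]) objects on one
#'   shared phase grid.
#' @param axisWeights length-2 positive weights for (phase, torque).
#' @param ... unused.
#' @return A single nonnegative number (mixed phase/torque units).
#' @rdname frechetDistance
#' @export
setMethod("frechetDistance", signature("GaitCurve", "GaitCurve"),
          function(x, y, axisWeights = c(1, 1), ...) {
  .checkSharedGrid(x, y)
  stopifnot(length(axisWeights) == 2L, all(axisWeights > 0))
  .frechetDP(x@phase, x@values, y@phase, y@values, axisWeights)
})

#' @rdname frechetDistance
#' @export
setMethod("frechetDistance", signature("TorqueProfile", "TorqueProfile"),
          function(x, y, axisWeights = c(1, 1), ...)
            frechetDistance(x@curve, y@curve, axisWeights = axisWeights))

#' Full similarity report between two profiles
#'
#' Convenience wrapper returning cosine similarity and discrete Frechet
#' distance together.
#'
#' @param x,y [TorqueProfile-class] objects on one shared phase grid.
#' @return A [SimilarityReport-class].
#' @export
similarityReport <- function(x, y) {
  new("SimilarityReport",
      cosineSimilarity = cosineSimilarity(x, y),
      frechetDistance = frechetDistance(x, y),
      nPoints = length(phasePoints(x)))
}
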