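## Ingestion and re-normalisation of gait-cycle curve tables. These define the
## grid and sign conventions every downstream module relies on: percent axes
## are 0-based and inclusive of both ends (101 points = exact 1% spacing), and
## velocities are lengthening-positive.

#' Read one gait-cycle curve from a comma-separated table
#'
#' Ingests one column of a digitized curve table (one header row, one phase
#' column plus value columns). Rows must have finite numeric cells and a
#' strictly increasing phase. Data digitized with a shortening-positive
#' convention can be flipped at ingestion with `negate = TRUE`, so that
#' everything downstream sees lengthening-positive velocities.
#'
#' @param path path to a csv file.
#' @param valueColumn name of the column holding the quantity.
#' @param quantity what the column measures (see [GaitCurve()]).
#' @param phaseKind `"stance"` or `"gait"`.
#' @param phaseColumn name of the phase column (default `"phase"`).
#' @param negate flip the sign of the values at ingestion.
#' @return A validated [GaitCurve-class].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(phase = c(0, 50, 100), torque = c(0, 1, 0)), f,
#'           row.names = FALSE)
#' readCurveTable(f, "torque", "joint_torque", "stance")
#' @export
readCurveTable <- function(path, valueColumn, quantity,
                           phaseKind = c("stance", "gait"),
                           phaseColumn = "phase", negate = FALSE) {
  phaseKind <- match.arg(phaseKind)
  if (!file.exists(path))
    stop("input file does not exist: ", path)
  tab <- utils::read.csv(path, check.names = FALSE)
  for (col in c(phaseColumn, valueColumn)) {
    if (!col %in% names(tab))
      stop(sprintf("column '%s' not found in %s (configuration error)", col, path))
  }
  ph <- suppressWarnings(as.numeric(tab[[phaseColumn]]))
  va <- suppressWarnings(as.numeric(tab[[valueColumn]]))
  bad <- which(!is.finite(ph) | !is.finite(va))
  if (length(bad))
    stop(sprintf("non-finite or non-numeric cell at data row %d of %s",
                 bad[1L], path))
  nonmono <- which(diff(ph) <= 0)
  if (length(nonmono))
    stop(sprintf("phase axis not strictly increasing at data row %d of %s",
                 nonmono[1L] + 1L, path))
  if (negate) va <- -va
  GaitCurve(ph, va, phaseKind = phaseKind, quantity = quantity)
}

#' Write a curve or torque profile as a comma-separated table
#'
#' Mirrors the ingestion dialect: a `phase` column plus one value column named
#' after the quantity.
#'
#' @param x a [GaitCurve-class] or [TorqueProfile-class].
#' @param path output csv path.
#' @return `path`, invisibly.
#' @export
writeCurveTable <- function(x, path) {
  if (is(x, "TorqueProfile")) x <- x@curve
  stopifnot(is(x, "GaitCurve"))
  tab <- data.frame(phase = x@phase, value = x@values)
  names(tab)[2L] <- x@quantity
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

.resampleCurve <- function(curve, nPoints) {
  nPoints <- as.integer(nPoints)
  if (nPoints < 2L) stop("nPoints must be at least 2")
  grid <- seq(0, 100, length.out = nPoints)
  v <- stats::approx(curve@phase, curve@values, xout = grid, rule = 2)$y
  initialize(curve, phase = grid, values = v)
}

#' Resample a curve onto a uniform 0--100 percent grid
#'
#' Linear interpolation onto `nPoints` equally spaced samples from 0 to 100
#' inclusive (101 points gives exact 1% increments). Phases outside the
#' source range are held at the nearest endpoint value.
#'
#' @param x a [GaitCurve-class], [TorqueProfile-class] or [MtuDynamics-class]
#'   (the latter resamples all three component curves).
#' @param nPoints number of output samples (default 101).
#' @param ... unused.
#' @return An object of the same class on the uniform grid.
#' @rdname resample
#' @export
setMethod("resample", "GaitCurve", function(x, nPoints = 101L, ...)
  .resampleCurve(x, nPoints))

#' @rdname resample
#' @export
setMethod("resample", "TorqueProfile", function(x, nPoints = 101L, ...)
  initialize(x, curve = .resampleCurve(x@curve, nPoints)))

#' @rdname resample
#' @export
setMethod("resample", "MtuDynamics", function(x, nPoints = 101L, ...)
  initialize(x, torque = .resampleCurve(x@torque, nPoints),
             fascicleVelocity = .resampleCurve(x@fascicleVelocity, nPoints),
             tendonVelocity = .resampleCurve(x@tendonVelocity, nPoints)))

.stanceToGaitCurve <- function(curve, toeOffPercent) {
  if (curve@phaseKind != "stance")
    stop("stanceToGait expects a stance-kind curve (state error)")
  if (!is.finite(toeOffPercent) || toeOffPercent <= 0 || toeOffPercent > 100)
    stop("toeOffPercent must lie in (0, 100]")
  initialize(curve, phase = curve@phase * toeOffPercent / 100,
             phaseKind = "gait")
}

.gaitToStanceCurve <- function(curve, toeOffPercent) {
  if (curve@phaseKind != "gait")
    stop("gaitToStance expects a gait-kind curve (state error)")
  if (!is.finite(toeOffPercent) || toeOffPercent <= 0 || toeOffPercent > 100)
    stop("toeOffPercent must lie in (0, 100]")
  ph <- curve@phase * 100 / toeOffPercent
  keep <- ph <= 100 + 1e-9
  if (sum(keep) < 2L)
    stop("curve has fewer than 2 samples before toe-off")
  initialize(curve, phase = pmin(ph[keep], 100), values = curve@values[keep],
             phaseKind = "stance")
}

#' Map percent-stance curves onto the percent-gait axis (and back)
#'
#' Stance-only data are placed on the full gait cycle by scaling the phase
#' axis so that 100% stance lands at the toe-off timing (walking default
#' 62.7% gait, the mean offset timing of the HITL reference study at
#' 1.25 m/s). Values are unchanged; swing samples are absent by construction,
#' so the output covers `[0, toeOffPercent]`. `gaitToStance` inverts the
#' mapping, dropping any samples beyond toe-off.
#'
#' @param x a [GaitCurve-class], [TorqueProfile-class] or [MtuDynamics-class].
#' @param toeOffPercent toe-off timing as percent of the gait cycle.
#' @return An object of the same class on the other phase axis.
#' @rdname stanceToGait
#' @export
setMethod("stanceToGait", "GaitCurve", function(x, toeOffPercent = 62.7)
  .stanceToGaitCurve(x, toeOffPercent))

#' @rdname stanceToGait
#' @export
setMethod("stanceToGait", "TorqueProfile", function(x, toeOffPercent = 62.7)
  initialize(x, curve = .stanceToGaitCurve(x@curve, toeOffPercent)))

#' @rdname stanceToGait
#' @export
setMethod("stanceToGait", "MtuDynamics", function(x, toeOffPercent = 62.7)
  initialize(x, torque = .stanceToGaitCurve(x@torque, toeOffPercent),
             fascicleVelocity = .stanceToGaitCurve(x@fascicleVelocity, toeOffPercent),
             tendonVelocity = .stanceToGaitCurve(x@tendonVelocity, toeOffPercent)))

#' @rdname stanceToGait
#' @export
setMethod("gaitToStance", "GaitCurve", function(x, toeOffPercent = 62.7)
  .gaitToStanceCurve(x, toeOffPercent))

#' @rdname stanceToGait
#' @export
setMethod("gaitToStance", "TorqueProfile", function(x, toeOffPercent = 62.7)
  initialize(x, curve = .gaitToStanceCurve(x@curve, toeOffPercent)))

#' @rdname stanceToGait
#' @export
setMethod("gaitToStance", "MtuDynamics", function(x, toeOffPercent = 62.7)
  initialize(x, torque = .gaitToStanceCurve(x@torque, toeOffPercent),
             fascicleVelocity = .gaitToStanceCurve(x@fascicleVelocity, toeOffPercent),
             tendonVelocity = .gaitToStanceCurve(x@tendonVelocity, toeOffPercent)))
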