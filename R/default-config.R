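## Parameter-file plumbing: controller configuration and reference-profile
## parameter sets are structured YAML, overridable per run. The bundled
## defaults are labelled synthetic where the source constants are not
## published (see the files under extdata/).

#' Path to a bundled parameter file
#'
#' @param name file name under the package's `extdata/` directory.
#' @return Absolute path.
#' @export
soleusExoFile <- function(name) {
  p <- system.file("extdata", name, package = "soleusExo", mustWork = FALSE)
  if (!nzchar(p)) stop("no bundled file named ", name)
  p
}

#' Default controller configuration for a gait type
#'
#' Reads the bundled (or a user-supplied) fiber parameter file and returns a
#' [ControllerConfig-class] with the gait-appropriate onset fraction (3.9%
#' walking, 8.8% running).
#'
#' @param gaitType `"walk"` or `"run"`.
#' @param paramFile YAML parameter file; the bundled synthetic defaults when
#'   missing.
#' @return A [ControllerConfig-class].
#' @examples
#' defaultControllerConfig("walk")
#' @export
defaultControllerConfig <- function(gaitType = c("walk", "run"),
                                    paramFile = NULL) {
  gaitType <- match.arg(gaitType)
  if (is.null(paramFile))
    paramFile <- soleusExoFile("fiber_params_synthetic.yaml")
  p <- yaml::read_yaml(paramFile)
  ControllerConfig(
    momentArm = p$moment_arm,
    composition = FiberComposition(p$composition$r_slow, p$composition$r_fast),
    corrections = EccentricCorrections(p$corrections$velocity_factor,
                                       p$corrections$force_factor),
    slowFiber = FiberParams(p$slow$M, p$slow$D),
    fastFiber = FiberParams(p$fast$M, p$fast$D),
    onsetFraction = p$onset_fraction[[gaitType]])
}

.paramsFromList <- function(x) {
  peak <- x$peak_torque
  HitlParams(x$onset_percent, x$peak_percent, x$offset_percent, peak,
             onsetTorque = if (!is.null(x$onset_torque)) x$onset_torque
             else x$onset_torque_fraction * peak)
}

#' Load a reference-profile parameter file
#'
#' Reads a YAML description of a HITL-style reference: mean parameters,
#' published key-point ranges, optional per-subject parameter sets (for
#' [hitlEnvelope()]) and optional EO speed anchors (for [eoParams()]).
#'
#' @param path YAML file; one of the bundled synthetic stand-ins when one of
#'   `"walk"`/`"run"` is given instead of a path.
#' @return A list with elements `study`, `gaitType`, `phaseKind`,
#'   `onsetFraction`, `toeOffPercent` (walking), `meanParams`
#'   ([HitlParams-class]), `range` (list of length-2 numeric), `subjects`
#'   (list of [HitlParams-class] or NULL) and `eoAnchors` (anchor list for
#'   [eoParams()] or NULL).
#' @examples
#' ref <- loadReferenceParams("walk")
#' ref$meanParams
#' @export
loadReferenceParams <- function(path) {
  if (path %in% c("walk", "run"))
    path <- soleusExoFile(sprintf("reference_%s_synthetic.yaml", path))
  r <- yaml::read_yaml(path)
  list(
    study = r$study,
    gaitType = r$gait_type,
    phaseKind = r$phase_kind,
    onsetFraction = r$onset_fraction,
    toeOffPercent = if (!is.null(r$toe_off_percent)) r$toe_off_percent else 100,
    meanParams = .paramsFromList(r$mean),
    range = lapply(r$range, as.numeric),
    subjects = if (!is.null(r$subjects))
      lapply(r$subjects, .paramsFromList),
    eoAnchors = if (!is.null(r$eo_anchors))
      lapply(r$eo_anchors, function(a)
        list(speed = a$speed, params = .paramsFromList(a))))
}
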