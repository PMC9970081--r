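## Seedable synthetic muscle-tendon dynamics. The generator emulates the
## qualitative morphology of soleus dynamics over stance — a unimodal
## late-stance torque bump with a small dorsiflexion dip after heel strike,
## tendon lengthening early in stance followed by recoil (shortening) near
## push-off, fascicle shortening that is slow through mid-stance and fast in
## late stance, plus an optional early-stance secondary fascicle mode seen at
## fast running — without attempting to fit any real data set. Curve
## primitives are raised-cosine bumps: smooth, compactly supported, and
## analytically evaluable so tests can use closed forms.

.bump <- function(phase, center, halfWidth, magnitude) {
  out <- numeric(length(phase))
  inside <- abs(phase - center) < halfWidth
  out[inside] <- magnitude * 0.5 *
    (1 + cos(pi * (phase[inside] - center) / halfWidth))
  out
}

## run expr with a private RNG stream; the global .Random.seed is untouched
.withSeed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  expr
}

#' SynthConfig: parameters of the synthetic dynamics generator
#'
#' All phases are percent of stance; magnitudes are nonnegative (velocity
#' magnitudes are *speeds*: the generated fascicle curve is
#' shortening-negative). `secondaryMag = 0` disables the early-stance
#' secondary fascicle mode.
#'
#' @slot gaitType `"walk"` or `"run"`.
#' @slot speed locomotion speed, m/s.
#' @slot nPoints stance grid size (default 101, 1% increments).
#' @slot torquePeakPhase,torquePeakMag,torqueWidth joint-torque bump: center
#'   (% stance), peak (Nm/kg) and half-width (%).
#' @slot tendonPeakPhase,tendonPeakMag early-stance tendon lengthening bump.
#' @slot tendonTroughPhase,tendonTroughDepth late-stance tendon recoil
#'   (shortening) bump; depth is the positive magnitude of the negative lobe.
#' @slot fasciclePeakPhase,fasciclePeakMag,fascicleWidth main late-stance
#'   fascicle shortening bump (speed magnitude).
#' @slot plateauMag broad slow-shortening plateau through mid-stance; sets a
#'   nonzero fascicle speed at the tendon-velocity peak and hence a nonzero
#'   deadband threshold.
#' @slot secondaryPhase,secondaryMag,secondaryWidth optional early-stance
#'   secondary fascicle shortening mode (fast running).
#' @slot noiseSd standard deviation of additive Gaussian noise on every
#'   curve (same units as the curve).
#' @slot seed RNG seed; identical configs give bitwise-identical output.
#' @exportClass SynthConfig
setClass("SynthConfig",
         representation(gaitType = "character", speed = "numeric",
                        nPoints = "integer",
                        torquePeakPhase = "numeric", torquePeakMag = "numeric",
                        torqueWidth = "numeric",
                        tendonPeakPhase = "numeric", tendonPeakMag = "numeric",
                        tendonTroughPhase = "numeric",
                        tendonTroughDepth = "numeric",
                        fasciclePeakPhase = "numeric",
                        fasciclePeakMag = "numeric", fascicleWidth = "numeric",
                        plateauMag = "numeric",
                        secondaryPhase = "numeric", secondaryMag = "numeric",
                        secondaryWidth = "numeric",
                        noiseSd = "numeric", seed = "integer"))

setValidity("SynthConfig", function(object) {
  msgs <- character()
  if (!object@gaitType %in% .GAIT_TYPES)
    msgs <- c(msgs, "gaitType must be 'walk' or 'run'")
  phases <- c(object@torquePeakPhase, object@tendonPeakPhase,
              object@tendonTroughPhase, object@fasciclePeakPhase,
              object@secondaryPhase)
  if (!all(is.finite(phases)) || any(phases <= 0) || any(phases >= 100))
    msgs <- c(msgs, "all bump phases must lie in (0, 100)")
  mags <- c(object@torquePeakMag, object@tendonPeakMag,
            object@tendonTroughDepth, object@fasciclePeakMag,
            object@plateauMag, object@secondaryMag)
  if (!all(is.finite(mags)) || any(mags < 0))
    msgs <- c(msgs, "all magnitudes must be nonnegative")
  if (!is.finite(object@noiseSd) || object@noiseSd < 0)
    msgs <- c(msgs, "noiseSd must be nonnegative")
  if (object@nPoints < 2L)
    msgs <- c(msgs, "nPoints must be at least 2")
  if (length(msgs)) msgs else TRUE
})

#' Construct a synthetic-dynamics configuration
#'
#' Defaults emulate soleus dynamics at the given gait type and speed: torque
#' and fascicle shortening speed grow with speed, the secondary early-stance
#' fascicle mode switches on for running at 4 m/s and above, and noise is off.
#' Any component can be overridden.
#'
#' @param gaitType `"walk"` or `"run"`.
#' @param speed locomotion speed, m/s.
#' @param torquePeakPhase,torquePeakMag,torqueWidth,tendonPeakPhase,tendonPeakMag,tendonTroughPhase,tendonTroughDepth,fasciclePeakPhase,fasciclePeakMag,fascicleWidth,plateauMag,secondaryPhase,secondaryMag,secondaryWidth,noiseSd,seed,nPoints
#'   see [SynthConfig-class] slots.
#' @return A [SynthConfig-class].
#' @examples
#' cfg <- SynthConfig("walk", 1.4, seed = 1L)
#' dyn <- synthDynamics(cfg)
#' @export
SynthConfig <- function(gaitType = c("walk", "run"), speed = 1.4,
                        torquePeakPhase = if (gaitType == "walk") 75 else 50,
                        torquePeakMag = if (gaitType == "walk")
                          1.1 + 0.25 * speed else 1.5 + 0.35 * speed,
                        torqueWidth = if (gaitType == "walk") 30 else 40,
                        tendonPeakPhase = if (gaitType == "walk") 35 else 25,
                        tendonPeakMag = if (gaitType == "walk")
                          0.4 + 0.2 * speed else 0.5 + 0.25 * speed,
                        tendonTroughPhase = 90,
                        tendonTroughDepth = if (gaitType == "walk")
                          1 + 0.5 * speed else 1 + 0.6 * speed,
                        fasciclePeakPhase = if (gaitType == "walk") 85 else 80,
                        fasciclePeakMag = if (gaitType == "walk")
                          0.2 + 0.5 * speed else 0.5 + 0.4 * speed,
                        fascicleWidth = if (gaitType == "walk") 15 else 20,
                        plateauMag = if (gaitType == "walk")
                          0.1 + 0.1 * speed else 0.15 + 0.05 * speed,
                        secondaryPhase = 12,
                        secondaryMag = if (gaitType == "run" && speed >= 4)
                          0.3 * speed - 0.6 else 0,
                        secondaryWidth = 10,
                        noiseSd = 0, seed = 1L, nPoints = 101L) {
  gaitType <- match.arg(gaitType)
  new("SynthConfig", gaitType = gaitType, speed = as.numeric(speed),
      nPoints = as.integer(nPoints),
      torquePeakPhase = torquePeakPhase, torquePeakMag = torquePeakMag,
      torqueWidth = torqueWidth,
      tendonPeakPhase = tendonPeakPhase, tendonPeakMag = tendonPeakMag,
      tendonTroughPhase = tendonTroughPhase,
      tendonTroughDepth = tendonTroughDepth,
      fasciclePeakPhase = fasciclePeakPhase,
      fasciclePeakMag = fasciclePeakMag, fascicleWidth = fascicleWidth,
      plateauMag = plateauMag,
      secondaryPhase = secondaryPhase, secondaryMag = secondaryMag,
      secondaryWidth = secondaryWidth,
      noiseSd = as.numeric(noiseSd), seed = as.integer(seed))
}

#' Generate synthetic muscle-tendon dynamics
#'
#' Builds an [MtuDynamics-class] on a uniform stance grid from raised-cosine
#' bump primitives per the configuration:
#' \itemize{
#'   \item joint torque: the planted unimodal bump plus a small (5% of peak)
#'     dorsiflexion-direction dip just after heel strike, so the `F < 0`
#'     controller branch is exercised;
#'   \item tendon velocity: a positive (lengthening) bump in early stance
#'     followed by a negative recoil bump near push-off;
#'   \item fascicle velocity: shortening-negative; a broad slow plateau
#'     through mid-stance, the main late-stance bump, and the optional
#'     early-stance secondary mode.
#' }
#' Identical configurations (including seed) produce bitwise-identical
#' output; the global RNG state is left untouched.
#'
#' @param config a [SynthConfig-class].
#' @return An [MtuDynamics-class] on the stance axis.
#' @export
synthDynamics <- function(config) {
  stopifnot(is(config, "SynthConfig"))
  validObject(config)
  ph <- seq(0, 100, length.out = config@nPoints)
  torque <- .bump(ph, config@torquePeakPhase, config@torqueWidth,
                  config@torquePeakMag) -
    .bump(ph, 4, 8, 0.05 * config@torquePeakMag)
  tendon <- .bump(ph, config@tendonPeakPhase, 25, config@tendonPeakMag) -
    .bump(ph, config@tendonTroughPhase, 15, config@tendonTroughDepth)
  fascicle <- -(.bump(ph, 45, 45, config@plateauMag) +
                .bump(ph, config@fasciclePeakPhase, config@fascicleWidth,
                      config@fasciclePeakMag) +
                .bump(ph, config@secondaryPhase, config@secondaryWidth,
                      config@secondaryMag))
  if (config@noiseSd > 0) {
    n <- length(ph)
    noise <- .withSeed(config@seed, stats::rnorm(3L * n, 0, config@noiseSd))
    torque <- torque + noise[seq_len(n)]
    tendon <- tendon + noise[n + seq_len(n)]
    fascicle <- fascicle + noise[2L * n + seq_len(n)]
  }
  MtuDynamics(
    GaitCurve(ph, torque, "stance", "joint_torque"),
    GaitCurve(ph, fascicle, "stance", "fascicle_velocity"),
    GaitCurve(ph, tendon, "stance", "tendon_velocity"),
    speed = config@speed, gaitType = config@gaitType)
}

#' Synthetic reference torque profile
#'
#' Test-fixture counterpart of [hitlCurve()]: builds the parameterized
#' reference waveform on the given grid (delegates to [hitlCurve()]).
#'
#' @inheritParams hitlCurve
#' @return A [TorqueProfile-class].
#' @export
synthReference <- function(params, grid = seq(0, 100, by = 1),
                           phaseKind = c("gait", "stance"))
  hitlCurve(params, grid, phaseKind = match.arg(phaseKind),
            controller = "HITL")
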