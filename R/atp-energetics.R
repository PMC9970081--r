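## ATP-hydrolysis-rate model of contracting fascicles. The rate-vs-speed
## relation is a saturating hyperbola with the resting (zero-velocity) rate
## subtracted, so only the ATP spent on motion remains:
##
##   As(v) = M * D * v / (1 + D * v),   v = |V_CE| / l0  (normalized speed)
##
## M is the asymptotic rate at infinite velocity; 1/D is the speed at which
## half of M is reached. Rates are in arbitrary units: peak-matching
## calibration downstream absorbs the scale.

#' ATP hydrolysis rate due to fascicle motion
#'
#' Saturating hyperbola of normalized fascicle speed with the static
#' (zero-velocity) rate removed: `M*D*v / (1 + D*v)`. Strictly increasing in
#' speed, zero at rest, bounded above by `M`.
#'
#' The argument is a *speed* (nonnegative): taking the absolute value of a
#' signed fascicle velocity is the caller's responsibility, which keeps the
#' signed/unsigned contract explicit. A negative input is a domain error.
#'
#' @param speedNorm nonnegative normalized fascicle speed, `|V_CE|/l0`
#'   (resting lengths per second). Vectorized.
#' @param fiber a [FiberParams-class].
#' @return ATP hydrolysis rate(s), arbitrary units.
#' @examples
#' atpRate(0.5, FiberParams(M = 1, D = 2))   # 0.5
#' atpRate(1 / 2, FiberParams(M = 1, D = 2)) # half-asymptote at speed 1/D
#' @export
atpRate <- function(speedNorm, fiber) {
  stopifnot(is(fiber, "FiberParams"))
  if (any(!is.finite(speedNorm)))
    stop("speedNorm must be finite")
  if (any(speedNorm < 0))
    stop("speedNorm must be nonnegative (pass a speed, not a signed velocity)")
  fiber@M * fiber@D * speedNorm / (1 + fiber@D * speedNorm)
}

#' Deadband-shifted ATP hydrolysis rate
#'
#' Speeds at or below `thresholdSpeed` are treated as zero velocity; above
#' it, the rate curve is shifted so it restarts from zero:
#' `atpRate(max(speedNorm - thresholdSpeed, 0), fiber)`. With a threshold of
#' zero this is identical to [atpRate()].
#'
#' @inheritParams atpRate
#' @param thresholdSpeed nonnegative normalized deadband speed (typically the
#'   fascicle speed at peak tendon lengthening velocity, see
#'   [deadbandSpeed()]).
#' @return ATP hydrolysis rate(s), arbitrary units.
#' @export
shiftedAtpRate <- function(speedNorm, thresholdSpeed, fiber) {
  if (length(thresholdSpeed) != 1L || !is.finite(thresholdSpeed) ||
      thresholdSpeed < 0)
    stop("thresholdSpeed must be a single nonnegative number")
  atpRate(pmax(speedNorm - thresholdSpeed, 0), fiber)
}

#' Net ATP hydrolysis rate of a mixed-fiber muscle
#'
#' Combines slow- and fast-fiber rates by the muscle's fiber composition and
#' applies the branch structure of the energetics model:
#' \itemize{
#'   \item zero wherever the muscle-tendon-unit force is negative (the muscle
#'     is not loaded in the assisted direction; only the *sign* of
#'     `mtuForce` is used);
#'   \item `rSlow*As_slow(|v|) + rFast*As_fast(|v|)` on the concentric branch
#'     (`vCe <= 0`, shortening);
#'   \item the same mixture multiplied by the eccentric velocity correction
#'     (default 1/2.7) where the fascicle lengthens (`vCe > 0`).
#' }
#' `As` is [atpRate()] in `"direct"` mode or [shiftedAtpRate()] in
#' `"shifted"` mode (the deadbanded controller), in which case
#' `thresholdSpeed` is required.
#'
#' @param vCe signed normalized fascicle velocity (lengthening positive).
#'   Vectorized.
#' @param mtuForce signed force; recycled against `vCe`. Only its sign
#'   matters here.
#' @param composition a [FiberComposition-class].
#' @param corrections an [EccentricCorrections-class].
#' @param fibers list with elements `slow` and `fast`, each a
#'   [FiberParams-class].
#' @param mode `"direct"` or `"shifted"`.
#' @param thresholdSpeed deadband speed, required when `mode = "shifted"`.
#' @return Net ATP hydrolysis rate(s), arbitrary units, nonnegative.
#' @examples
#' fib <- list(slow = FiberParams(1, 2), fast = FiberParams(1, 2))
#' netAtpRate(-0.5, 1, FiberComposition(0.8), EccentricCorrections(), fib)
#' @export
netAtpRate <- function(vCe, mtuForce, composition = FiberComposition(),
                       corrections = EccentricCorrections(),
                       fibers, mode = c("direct", "shifted"),
                       thresholdSpeed = NULL) {
  mode <- match.arg(mode)
  stopifnot(is(composition, "FiberComposition"),
            is(corrections, "EccentricCorrections"),
            is.list(fibers), all(c("slow", "fast") %in% names(fibers)))
  if (mode == "shifted" && is.null(thresholdSpeed))
    stop("mode = 'shifted' requires thresholdSpeed (configuration error)")
  n <- max(length(vCe), length(mtuForce))
  vCe <- rep_len(vCe, n)
  mtuForce <- rep_len(mtuForce, n)
  speed <- abs(vCe)
  as1 <- if (mode == "direct") atpRate(speed, fibers$slow) else
    shiftedAtpRate(speed, thresholdSpeed, fibers$slow)
  as2 <- if (mode == "direct") atpRate(speed, fibers$fast) else
    shiftedAtpRate(speed, thresholdSpeed, fibers$fast)
  rate <- composition@rSlow * as1 + composition@rFast * as2
  rate[vCe > 0] <- rate[vCe > 0] * corrections@velocityFactor
  rate[mtuForce < 0] <- 0
  rate
}
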