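#' Generate a stimulated-exocytosis pHluorin trace
#'
#' Piecewise trace emulating a pHluorin dequench experiment: flat basal
#' fluorescence, a saturating rise after stimulation to
#' \code{basal + stimRiseFraction * (nh4cl - basal)}, and a step to the
#' NH4Cl plateau once all intracellular compartments are neutralized. The
#' rise follows a smoothstep ramp that reaches the stimulated plateau
#' exactly after \code{riseTime} seconds, so noiseless traces close the
#' loop with \code{\link{percentExocytosis}} exactly. An optional
#' reacidification term models endocytic re-quenching of exocytosed
#' reporter (suppressed experimentally by bafilomycin); with
#' \code{reacidRate = 0} the trace is unchanged.
#'
#' @param basalLevel basal fluorescence (a.u.), must be < \code{nh4clLevel}.
#' @param stimRiseFraction fraction in [0, 1] of the dynamic range reached
#'   by stimulation; the ground-truth percent exocytosis is 100 times this.
#' @param nh4clLevel post-NH4Cl plateau (a.u.).
#' @param tStim,tNH4Cl stimulation and NH4Cl times (s); must satisfy
#'   \code{tStim < tNH4Cl < duration}.
#' @param duration,dt trace length and sampling interval (s).
#' @param riseTime seconds over which the stimulated rise completes.
#' @param reacidRate per-second decay rate of the stimulated component
#'   (reacidification); 0 disables it.
#' @param tBaf optional bafilomycin annotation (s) copied onto the trace.
#' @param cfg a \code{\link{genConfig}}; \code{noiseSd} is in a.u.
#' @return list with elements \code{trace} (\linkS4class{TimeSeriesTrace})
#'   and \code{truth} (list with \code{truePctExocytosis} etc.).
#' @examples
#' g <- genExoTrace(stimRiseFraction = 0.25)
#' g$truth$truePctExocytosis  # 25
#' @export
genExoTrace <- function(basalLevel = 100, stimRiseFraction = 0.5,
                        nh4clLevel = 300, tStim = 20, tNH4Cl = 420,
                        duration = 600, dt = 2, riseTime = 120,
                        reacidRate = 0, tBaf = NA_real_,
                        cfg = genConfig()) {
  if (basalLevel >= nh4clLevel)
    stop("basalLevel must be below nh4clLevel")
  if (stimRiseFraction < 0 || stimRiseFraction > 1)
    stop("stimRiseFraction must lie in [0, 1]")
  if (!(tStim < tNH4Cl && tNH4Cl < duration))
    stop("invalid annotation: need tStim < tNH4Cl < duration")
  tt <- seq(0, duration, by = dt)
  amp <- stimRiseFraction * (nh4clLevel - basalLevel)
  s <- pmin(pmax((tt - tStim) / riseTime, 0), 1)
  ramp <- 3 * s^2 - 2 * s^3
  vv <- basalLevel + amp * ramp * exp(-reacidRate * pmax(tt - tStim, 0))
  vv[tt >= tNH4Cl] <- nh4clLevel
  vv <- with_seed(cfg$seed, vv + stats::rnorm(length(vv), 0, cfg$noiseSd))
  trace <- TimeSeriesTrace(tt, vv, tStim = tStim, tNH4Cl = tNH4Cl,
                           tBaf = tBaf, id = "synthetic-exo")
  list(trace = trace,
       truth = list(truePctExocytosis = 100 * stimRiseFraction,
                    basalLevel = basalLevel,
                    stimPlateau = basalLevel + amp,
                    nh4clLevel = nh4clLevel))
}

#' Generate a FITC-quench endocytosis curve
#'
#' Exponential-to-plateau quench curve emulating receptor internalization
#' monitored by FITC fluorescence quenching:
#' \code{F(t) = 1 - q * (1 - exp(-rate * t))} for t >= 0, with F = 1 before
#' stimulation at t = 0.
#'
#' @param quenchFraction asymptotic quenched fraction q in [0, 1].
#' @param rate quench rate (1/s).
#' @param duration post-stimulation duration (s).
#' @param preStim seconds of pre-stimulation baseline (t < 0).
#' @param dt sampling interval (s).
#' @param cfg a \code{\link{genConfig}}; \code{noiseSd} is on the
#'   normalized (unit baseline) scale.
#' @return list(trace = \linkS4class{TimeSeriesTrace} with tStim = 0,
#'   truth = list(trueQuenchFraction, rate)).
#' @export
genQuenchCurve <- function(quenchFraction = 0.5, rate = 0.003,
                           duration = 1500, preStim = 60, dt = 5,
                           cfg = genConfig()) {
  if (quenchFraction < 0 || quenchFraction > 1)
    stop("quenchFraction must lie in [0, 1]")
  if (rate < 0) stop("rate must be nonnegative")
  tt <- seq(-preStim, duration, by = dt)
  vv <- ifelse(tt < 0, 1, 1 - quenchFraction * (1 - exp(-rate * tt)))
  vv <- with_seed(cfg$seed, vv + stats::rnorm(length(vv), 0, cfg$noiseSd))
  trace <- TimeSeriesTrace(tt, vv, tStim = 0, id = "synthetic-quench")
  list(trace = trace,
       truth = list(trueQuenchFraction = quenchFraction, rate = rate))
}
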