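## Ex vivo force computations for isolated muscle strips: cross-sectional
## area and specific force, twitch averaging, eccentric-contraction decay,
## post-protocol recovery, stiffness, and longitudinal percent changes.

#' @describeIn accessors estimated cross-sectional area of a
#'   [MusclePrep-class] in cm^2: `mass / (l0 * lengthToFiberRatio * density)`
#'   — the standard wet-mass CSA estimate (mass over fiber length times
#'   density).
#' @export
setMethod("crossSectionalArea", "MusclePrep", function(x) {
  x@mass / (x@l0 * x@lengthToFiberRatio * x@density)
})

#' Specific force
#'
#' Normalises an absolute force to the estimated muscle cross-sectional
#' area: `sP = P / CSA`, with `P` in N and CSA in cm^2, expressed in kN/m^2
#' (1 N/cm^2 = 10 kN/m^2). The printed form of this normalisation,
#' `sP = P / (Mass / (Lf * D))`, is the same quantity: mass over fiber
#' length times density is the CSA estimate of [crossSectionalArea()].
#'
#' @param pNewton absolute force in N (>= 0).
#' @param csa cross-sectional area in cm^2 (> 0), e.g. from
#'   [crossSectionalArea()].
#' @return Specific force in kN/m^2.
#' @examples
#' specificForce(0.5, 0.01) # 500 kN/m^2
#' @export
specificForce <- function(pNewton, csa) {
  if (any(!is.finite(csa)) || any(csa <= 0)) {
    stop("cross-sectional area must be positive")
  }
  if (any(pNewton < 0)) {
    stop("force must be non-negative")
  }
  pNewton / csa * 10
}

#' Mean twitch force
#'
#' Maximal twitch tension as the mean of repeated twitches, conventionally
#' 5; a different count triggers a warning.
#'
#' @param forces numeric vector of twitch forces (any consistent unit).
#' @return Their arithmetic mean.
#' @export
meanTwitch <- function(forces) {
  stopifnot(length(forces) >= 1L, all(is.finite(forces)))
  if (length(forces) != 5L) {
    warning(sprintf("twitch tension conventionally averages 5 twitches; got %d", length(forces)))
  }
  mean(forces)
}

#' Eccentric-contraction force decay
#'
#' Progressive decay of isometric force over a series of 10 eccentric
#' contractions: the percent reduction at the 5th and 10th pulse relative
#' to the 1st, `100 * (F1 - Fk) / F1`.
#'
#' @param pulseForces numeric vector of per-pulse isometric forces indexed
#'   1..10 (at least pulses 1, 5 and 10 must be present and finite;
#'   `F1 > 0`).
#' @return Named vector `c(decay5 = , decay10 = )` in percent.
#' @examples
#' eccentricDecay(c(100, 90, 82, 75, 70, 65, 60, 56, 53, 50)) # 30, 50
#' @export
eccentricDecay <- function(pulseForces) {
  if (length(pulseForces) < 10L) {
    stop("need forces for pulses 1..10")
  }
  f <- pulseForces[c(1L, 5L, 10L)]
  if (any(!is.finite(f))) {
    stop("pulses 1, 5 and 10 must be present and finite")
  }
  if (f[1L] <= 0) {
    stop("force at the 1st pulse must be positive")
  }
  c(
    decay5 = 100 * (f[1L] - f[2L]) / f[1L],
    decay10 = 100 * (f[1L] - f[3L]) / f[1L]
  )
}

#' Recovery after the eccentric protocol
#'
#' Percent of the pre-protocol tetanic force recovered at 4 and 30 minutes
#' after the eccentric series: `100 * Ft / Fpre`.
#'
#' @param preProtocol tetanic force before the protocol (> 0).
#' @param at4min,at30min tetanic forces 4 and 30 minutes after.
#' @return Named vector `c(rec4 = , rec30 = )` in percent.
#' @export
forceRecovery <- function(preProtocol, at4min, at30min) {
  if (!is.finite(preProtocol) || preProtocol <= 0) {
    stop("pre-protocol force must be positive")
  }
  c(rec4 = 100 * at4min / preProtocol, rec30 = 100 * at30min / preProtocol)
}

#' Dynamic stiffness at an eccentric stimulus
#'
#' Difference in isometric force produced before and after the stretch,
#' normalised by a reference muscle volume: `(Fafter - Fbefore) / V` in
#' mN/mm^3. The reference volume is caller-supplied; the conventional
#' default is the muscle volume `mass / density` (see
#' [defaultStiffnessVolume()]). Vectorised over stimuli.
#'
#' @param forceAfter,forceBefore isometric force after/before the stretch
#'   (mN).
#' @param referenceVolume normalising volume in mm^3 (> 0).
#' @return Stiffness in mN/mm^3.
#' @examples
#' muscleStiffness(130, 100, 10) # 3 mN/mm^3
#' @export
muscleStiffness <- function(forceAfter, forceBefore, referenceVolume) {
  if (any(!is.finite(referenceVolume)) || any(referenceVolume <= 0)) {
    stop("reference volume must be positive")
  }
  (forceAfter - forceBefore) / referenceVolume
}

#' Default stiffness reference volume
#'
#' Muscle volume from wet mass and density, `mass / density`, converted to
#' mm^3 (1 cm^3 = 1000 mm^3).
#'
#' @param prep a [MusclePrep-class].
#' @return Volume in mm^3.
#' @export
defaultStiffnessVolume <- function(prep) {
  stopifnot(is(prep, "MusclePrep"))
  prep@mass / prep@density * 1000
}

#' Percent change between two timepoints
#'
#' `100 * (value6 - value3) / value3`, the longitudinal delta of a readout
#' between e.g. 3 and 6 months of age. Reported to one decimal in printed
#' summaries.
#'
#' @param value3 reference (earlier) value, nonzero.
#' @param value6 later value.
#' @return Percent change (full precision).
#' @examples
#' percentChange(0.139, 0.123) # -11.5
#' percentChange(269, 183) # -32.0
#' @export
percentChange <- function(value3, value6) {
  if (any(!is.finite(value3)) || any(value3 == 0)) {
    stop("reference value must be nonzero")
  }
  100 * (value6 - value3) / value3
}

#' Group-level percent change
#'
#' Longitudinal percent change for a group of animals, either as the change
#' of the group means (`"means"`, the default) or as the mean of per-animal
#' changes (`"per_animal"`, which requires the two vectors to be paired by
#' animal). The two modes differ whenever animals vary in baseline.
#'
#' @param values3,values6 per-animal values at the earlier/later timepoint.
#' @param mode `"means"` or `"per_animal"`.
#' @return Percent change (full precision).
#' @export
groupPercentChange <- function(values3, values6,
                               mode = c("means", "per_animal")) {
  mode <- match.arg(mode)
  switch(mode,
    means = percentChange(mean(values3), mean(values6)),
    per_animal = {
      if (length(values3) != length(values6)) {
        stop("per-animal mode requires paired vectors of equal length")
      }
      mean(percentChange(values3, values6))
    }
  )
}
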