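## Synthetic-data generators: B-mode phantoms with a hyperechoic abdominal
## wall band and a configurable depth-attenuation law, M-mode breathing
## traces, and correlated cohort tables. Every generator carries its ground
## truth so downstream estimators have recovery tests.

.clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' Ground truth for a B-mode phantom
#'
#' Describes a frame with a bright superficial abdominal-wall (AW) band over
#' a dimmer background, a linear attenuation law linking the intensity below
#' the band to the band thickness, and multiplicative speckle.
#'
#' The expected intensity is `awIntensity` inside the band rows and
#' `belowBaseIntensity + attenuationSlope * awThickness * awIntensity`
#' (clamped to \[0, 1\]) below it; a negative slope makes thicker walls shade
#' the tissue underneath. Speckle multiplies every pixel by
#' `1 + speckleCV * z`, `z ~ N(0, 1)`.
#'
#' @param awTopRow first image row (1-based) of the AW band.
#' @param awThickness band thickness in pixels (>= 1).
#' @param awIntensity expected band intensity, fraction of full scale in \[0, 1\].
#' @param belowBaseIntensity background intensity before attenuation, in \[0, 1\].
#' @param attenuationSlope change in below-band intensity (as a fraction of
#'   `awIntensity`) per pixel of AW thickness; 0 = no attenuation.
#' @param speckleCV coefficient of variation of the multiplicative speckle
#'   (>= 0; 0 = noise-free).
#' @param seed integer RNG seed.
#' @return A validated `bmodeTruth` list.
#' @export
bmodeTruth <- function(awTopRow = 16L, awThickness = 20L, awIntensity = 0.9,
                       belowBaseIntensity = 0.35, attenuationSlope = 0,
                       speckleCV = 0.05, seed = 1L) {
  t <- list(
    awTopRow = as.integer(awTopRow), awThickness = as.integer(awThickness),
    awIntensity = awIntensity, belowBaseIntensity = belowBaseIntensity,
    attenuationSlope = attenuationSlope, speckleCV = speckleCV,
    seed = as.integer(seed)
  )
  stopifnot(
    t$awTopRow >= 1L, t$awThickness >= 1L,
    t$awIntensity >= 0, t$awIntensity <= 1,
    t$belowBaseIntensity >= 0, t$belowBaseIntensity <= 1,
    t$speckleCV >= 0
  )
  structure(t, class = "bmodeTruth")
}

#' Simulate a B-mode phantom frame
#'
#' Builds the expected-intensity pattern of [bmodeTruth()] and applies
#' multiplicative speckle, clamped to \[0, 1\]. Deterministic under the
#' truth's seed.
#'
#' @param truth a [bmodeTruth()].
#' @param height,width frame dimensions in pixels. The geometry must leave
#'   at least 50 rows below the band (room for the below-AW window).
#' @param belowWindow rows that must remain under the band (default 50).
#' @return An [UltrasoundFrame-class] with `scale = "normalized_0_1"`.
#' @examples
#' simulateBMode(bmodeTruth(speckleCV = 0), height = 120, width = 40)
#' @export
simulateBMode <- function(truth, height, width, belowWindow = 50L) {
  stopifnot(inherits(truth, "bmodeTruth"))
  bandEnd <- truth$awTopRow + truth$awThickness - 1L
  if (height - bandEnd < belowWindow) {
    stop(
      "frame geometry leaves fewer than ", belowWindow,
      " rows below the AW band"
    )
  }
  belowI <- .clamp01(
    truth$belowBaseIntensity +
      truth$attenuationSlope * truth$awThickness * truth$awIntensity
  )
  rowI <- rep(truth$belowBaseIntensity, height)
  rowI[truth$awTopRow:bandEnd] <- truth$awIntensity
  if (bandEnd < height) rowI[(bandEnd + 1L):height] <- belowI
  px <- matrix(rowI, nrow = height, ncol = width)
  if (truth$speckleCV > 0) {
    set.seed(truth$seed)
    px <- .clamp01(px * (1 + truth$speckleCV * stats::rnorm(length(px))))
  }
  UltrasoundFrame(px,
    scale = "normalized_0_1",
    sourceId = sprintf(
      "phantom_t%d_s%d", truth$awThickness, truth$seed
    )
  )
}

#' Simulate a multi-thickness B-mode phantom set
#'
#' Generates one frame per requested band thickness, sharing all other
#' ground-truth parameters; the thickness variation is what lets the
#' attenuation analysis fit ratio against thickness.
#'
#' @param thicknesses integer vector of AW thicknesses (pixels), one frame each.
#' @param height,width frame dimensions.
#' @param seed base seed; frame i uses `seed + i`.
#' @param ... further arguments to [bmodeTruth()] (intensities, slope,
#'   speckle).
#' @return A list of [UltrasoundFrame-class] objects.
#' @export
simulateBModeSet <- function(thicknesses, height, width, seed = 1L, ...) {
  lapply(seq_along(thicknesses), function(i) {
    simulateBMode(
      bmodeTruth(awThickness = thicknesses[i], seed = seed + i, ...),
      height = height, width = width
    )
  })
}

#' Ground truth for an M-mode breathing trace
#'
#' @param baselineMm expiratory baseline position (mm).
#' @param amplitudeMm inspiratory deflection peak (mm), > 0.
#' @param breathsPerMin breathing rate (min^-1).
#' @param noiseSdMm additive Gaussian noise SD (mm).
#' @param nBreaths number of breaths (>= 3).
#' @param inspFraction fraction of the cycle spent in inspiration (the
#'   half-sine deflection occupies this fraction of each period).
#' @param seed integer RNG seed.
#' @return A validated `mmodeTruth` list.
#' @export
mmodeTruth <- function(baselineMm = 0, amplitudeMm = 0.9, breathsPerMin = 150,
                       noiseSdMm = 0.05, nBreaths = 8L, inspFraction = 0.4,
                       seed = 1L) {
  t <- list(
    baselineMm = baselineMm, amplitudeMm = amplitudeMm,
    breathsPerMin = breathsPerMin, noiseSdMm = noiseSdMm,
    nBreaths = as.integer(nBreaths), inspFraction = inspFraction,
    seed = as.integer(seed)
  )
  stopifnot(
    t$amplitudeMm >= 0, t$breathsPerMin > 0, t$noiseSdMm >= 0,
    t$nBreaths >= 3L, t$inspFraction > 0, t$inspFraction < 1
  )
  structure(t, class = "mmodeTruth")
}

#' Simulate an M-mode diaphragm position trace
#'
#' Baseline plus periodic half-sine positive deflections (one per breath)
#' plus additive Gaussian noise. Deterministic under the truth's seed.
#'
#' @param truth an [mmodeTruth()].
#' @param sampleRate sampling rate in Hz; must resolve a breath with at
#'   least 10 samples per cycle.
#' @param duration trace length in seconds; defaults to exactly `nBreaths`
#'   cycles and must cover at least that many.
#' @return An [MModeTrace-class].
#' @examples
#' simulateMMode(mmodeTruth(noiseSdMm = 0), sampleRate = 200)
#' @export
simulateMMode <- function(truth, sampleRate = 200, duration = NULL) {
  stopifnot(inherits(truth, "mmodeTruth"))
  period <- 60 / truth$breathsPerMin
  if (is.null(duration)) duration <- truth$nBreaths * period
  if (duration < truth$nBreaths * period - 1e-9) {
    stop("duration too short to cover ", truth$nBreaths, " breaths")
  }
  if (sampleRate * period < 10) {
    stop("sample rate too low to resolve a breath (need >= 10 samples/cycle)")
  }
  n <- round(duration * sampleRate)
  tm <- (seq_len(n) - 1L) / sampleRate
  phase <- tm %% period
  ti <- truth$inspFraction * period
  defl <- ifelse(phase < ti, truth$amplitudeMm * sin(pi * phase / ti), 0)
  pos <- truth$baselineMm + defl
  if (truth$noiseSdMm > 0) {
    set.seed(truth$seed)
    pos <- pos + stats::rnorm(n, sd = truth$noiseSdMm)
  }
  MModeTrace(tm, pos, sampleRate = sampleRate)
}

#' Specification of a synthetic cohort
#'
#' Defines a set of animal groups (e.g. wt/mdx at two ages) with per-group
#' means and SDs for each readout and a common exchangeable correlation
#' between readouts within an animal.
#'
#' @param groups named list; each element is a list with `n` (>= 2) and
#'   named numeric vectors `mean` and `sd` (same readout names across
#'   groups, `sd >= 0`).
#' @param correlation common pairwise correlation between readouts,
#'   in \[-1, 1\]. Must give a positive semi-definite matrix for the number
#'   of readouts.
#' @param seed integer RNG seed.
#' @return A validated `cohortSpec` list.
#' @examples
#' cohortSpec(list(
#'   wt  = list(n = 9, mean = c(amp = 0.61, dist = 430), sd = c(amp = 0.05, dist = 35)),
#'   mdx = list(n = 9, mean = c(amp = 0.37, dist = 269), sd = c(amp = 0.05, dist = 19))
#' ), correlation = 0.6)
#' @export
cohortSpec <- function(groups, correlation = 0, seed = 1L) {
  stopifnot(is.list(groups), length(groups) >= 1L, !is.null(names(groups)))
  readouts <- names(groups[[1L]]$mean)
  for (g in groups) {
    stopifnot(
      g$n >= 2L, identical(names(g$mean), readouts),
      identical(names(g$sd), readouts), all(g$sd >= 0)
    )
  }
  stopifnot(abs(correlation) <= 1)
  k <- length(readouts)
  R <- matrix(correlation, k, k)
  diag(R) <- 1
  if (k > 1L && min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) <
    -1e-8) {
    stop("correlation structure is not positive semi-definite")
  }
  structure(
    list(
      groups = groups, readouts = readouts, correlation = R,
      seed = as.integer(seed)
    ),
    class = "cohortSpec"
  )
}

#' Simulate a cohort table with correlated readouts
#'
#' Draws each animal's readouts from a multivariate Gaussian with the
#' group's means/SDs and the spec's readout correlation
#' (via [MASS::mvrnorm()]). Deterministic under the spec's seed.
#'
#' @param spec a [cohortSpec()].
#' @return A data.frame with columns `animal_id`, `group` and one column per
#'   readout.
#' @export
simulateCohort <- function(spec) {
  stopifnot(inherits(spec, "cohortSpec"))
  set.seed(spec$seed)
  k <- length(spec$readouts)
  out <- lapply(names(spec$groups), function(gname) {
    g <- spec$groups[[gname]]
    Sigma <- diag(g$sd, k, k) %*% spec$correlation %*% diag(g$sd, k, k)
    x <- MASS::mvrnorm(g$n, mu = g$mean, Sigma = Sigma, tol = 1e-6)
    x <- matrix(x, nrow = g$n, dimnames = list(NULL, spec$readouts))
    data.frame(
      animal_id = sprintf("%s_%02d", gname, seq_len(g$n)),
      group = gname, x,
      stringsAsFactors = FALSE, row.names = NULL
    )
  })
  do.call(rbind, out)
}
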