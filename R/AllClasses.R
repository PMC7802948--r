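#' @import methods
NULL

## Intensity scales an UltrasoundFrame can carry. Raw frames hold 8-bit
## grayscale values; normalized frames are divided by their own maximum so the
## brightest pixel is exactly 1.
.FRAME_SCALES <- c("raw_0_255", "normalized_0_1")

#' UltrasoundFrame: a single B-mode still (or any 2-D intensity grid)
#'
#' The substrate of all image operations in the package. Pixels are stored as
#' a numeric matrix in row-major image orientation: row 1 is the shallowest
#' depth (top of the image), columns run laterally across the probe face.
#'
#' @slot pixels numeric matrix of intensities.
#' @slot scale either `"raw_0_255"` (8-bit grayscale) or `"normalized_0_1"`
#'   (divided by the frame maximum).
#' @slot mmPerPixel physical pixel pitch in mm, or `NA_real_` when unknown.
#' @slot sourceId free-text identifier (file name, phantom label, ...).
#'
#' @seealso [loadFrame()], [normalizeFrame()], [cropFrame()]
#' @exportClass UltrasoundFrame
setClass("UltrasoundFrame",
  representation(
    pixels = "matrix",
    scale = "character",
    mmPerPixel = "numeric",
    sourceId = "character"
  ),
  prototype(
    pixels = matrix(0, 1, 1),
    scale = "raw_0_255",
    mmPerPixel = NA_real_,
    sourceId = ""
  )
)

setValidity("UltrasoundFrame", function(object) {
  px <- object@pixels
  if (!is.numeric(px)) {
    return("pixels must be a numeric matrix")
  }
  if (nrow(px) < 1L || ncol(px) < 1L) {
    return("pixel grid must be non-empty")
  }
  if (anyNA(px)) {
    return("pixel grid contains NA")
  }
  if (length(object@scale) != 1L || !object@scale %in% .FRAME_SCALES) {
    return(sprintf(
      "scale must be one of: %s", paste(.FRAME_SCALES, collapse = ", ")
    ))
  }
  hi <- if (object@scale == "raw_0_255") 255 else 1
  if (min(px) < 0 || max(px) > hi) {
    return(sprintf("intensities outside [0, %s] for scale '%s'", hi, object@scale))
  }
  if (length(object@mmPerPixel) != 1L) {
    return("mmPerPixel must be a single number (NA allowed)")
  }
  TRUE
})

#' Construct an UltrasoundFrame
#'
#' @param pixels numeric matrix; row 1 = top of image (shallowest depth).
#' @param scale `"raw_0_255"` or `"normalized_0_1"`.
#' @param mmPerPixel physical pixel pitch in mm (`NA` if unknown).
#' @param sourceId identifier carried through the pipeline.
#' @return An [UltrasoundFrame-class] object.
#' @examples
#' f <- UltrasoundFrame(matrix(0:255, 16, 16), scale = "raw_0_255")
#' f
#' @export
UltrasoundFrame <- function(pixels, scale = c("raw_0_255", "normalized_0_1"),
                            mmPerPixel = NA_real_, sourceId = "") {
  scale <- match.arg(scale)
  new("UltrasoundFrame",
    pixels = pixels, scale = scale,
    mmPerPixel = as.numeric(mmPerPixel), sourceId = as.character(sourceId)
  )
}

#' ROI: a region of interest congruent with a frame
#'
#' A boolean mask over the pixel grid of one [UltrasoundFrame-class].
#'
#' @slot mask logical matrix; `TRUE` marks pixels inside the region.
#' @exportClass ROI
setClass("ROI", representation(mask = "matrix"))

setValidity("ROI", function(object) {
  m <- object@mask
  if (!is.logical(m)) {
    return("mask must be a logical matrix")
  }
  if (anyNA(m)) {
    return("mask contains NA")
  }
  if (sum(m) < 1L) {
    return("ROI must contain at least one pixel")
  }
  TRUE
})

#' Construct an ROI from a logical mask
#'
#' @param mask logical matrix, same dimensions as the frame it will be
#'   applied to; `TRUE` = inside the region.
#' @return An [ROI-class] object.
#' @export
ROI <- function(mask) {
  storage.mode(mask) <- "logical"
  new("ROI", mask = mask)
}

#' EchodensityResult: grayscale summary of one outlined region
#'
#' First-order grayscale statistics of the pixels inside an ROI on the 8-bit
#' (0-255) scale: the mean pixel intensity ("echodensity"), the full 256-bin
#' histogram and the pixel count.
#'
#' @slot meanPI mean pixel intensity of the ROI on the 0-255 scale.
#' @slot histogram integer vector of 256 counts (bin i = intensity i-1).
#' @slot pixelCount number of pixels inside the ROI.
#' @slot frameIds identifiers of the frames that contributed.
#' @exportClass EchodensityResult
setClass("EchodensityResult",
  representation(
    meanPI = "numeric",
    histogram = "integer",
    pixelCount = "integer",
    frameIds = "character"
  )
)

setValidity("EchodensityResult", function(object) {
  if (length(object@histogram) != 256L) {
    return("histogram must have 256 bins")
  }
  if (sum(object@histogram) != object@pixelCount) {
    return("histogram counts must sum to pixelCount")
  }
  if (object@meanPI < 0 || object@meanPI > 255) {
    return("meanPI must lie in [0, 255]")
  }
  wmean <- sum((0:255) * object@histogram) / object@pixelCount
  if (abs(wmean - object@meanPI) > 1e-8) {
    return("meanPI must equal the histogram-weighted mean")
  }
  TRUE
})

#' MModeTrace: diaphragm position versus time
#'
#' A digitised M-mode trace. Position is expressed so that inspiration is a
#' positive deflection (mm above the expiratory baseline).
#'
#' @slot time sampling times in seconds, strictly increasing.
#' @slot position diaphragm position in mm.
#' @slot sampleRate sampling rate in Hz.
#' @exportClass MModeTrace
setClass("MModeTrace",
  representation(time = "numeric", position = "numeric", sampleRate = "numeric")
)

setValidity("MModeTrace", function(object) {
  if (length(object@time) != length(object@position)) {
    return("time and position must have equal length")
  }
  if (length(object@time) < 2L) {
    return("trace must have at least 2 samples")
  }
  if (any(diff(object@time) <= 0)) {
    return("time must be strictly increasing")
  }
  if (length(object@sampleRate) != 1L || !is.finite(object@sampleRate) ||
    object@sampleRate <= 0) {
    return("sampleRate must be a positive number")
  }
  TRUE
})

#' Construct an MModeTrace
#'
#' @param time seconds, strictly increasing.
#' @param position mm; inspiration = positive deflection.
#' @param sampleRate Hz; inferred from `time` when omitted.
#' @return An [MModeTrace-class] object.
#' @export
MModeTrace <- function(time, position, sampleRate = NULL) {
  if (is.null(sampleRate)) {
    sampleRate <- 1 / stats::median(diff(time))
  }
  new("MModeTrace",
    time = as.numeric(time), position = as.numeric(position),
    sampleRate = as.numeric(sampleRate)
  )
}

#' AmplitudeResult: per-inspiration diaphragm amplitudes
#'
#' @slot perBreath amplitudes (mm) of the breaths used.
#' @slot meanAmplitude mean of `perBreath` in mm.
#' @slot nUsed number of breaths averaged.
#' @exportClass AmplitudeResult
setClass("AmplitudeResult",
  representation(
    perBreath = "numeric", meanAmplitude = "numeric", nUsed = "integer"
  )
)

setValidity("AmplitudeResult", function(object) {
  if (object@nUsed != length(object@perBreath)) {
    return("nUsed must equal length(perBreath)")
  }
  if (object@nUsed < 1L) {
    return("at least one breath is required")
  }
  if (abs(object@meanAmplitude - mean(object@perBreath)) > 1e-12) {
    return("meanAmplitude must be the arithmetic mean of perBreath")
  }
  TRUE
})

#' AttenuationDataset: consolidated per-column abdominal-wall records
#'
#' Pooled result of the per-column abdominal wall (AW) analysis over one or
#' more B-mode images, with the Pearson correlation between the
#' below-AW/AW intensity ratio and the AW thickness.
#'
#' @slot records data.frame with one row per accepted pixel column
#'   (image_id, column, top_edge_row, bottom_edge_row, aw_thickness,
#'   aw_mean_pi, below_aw_pi, ratio).
#' @slot nColumns number of accepted columns (rows of `records`).
#' @slot nPixelsAnalyzed total pixels entering the metrics
#'   (sum over columns of thickness + below-window).
#' @slot r Pearson correlation of (aw_thickness, ratio).
#' @slot rSquared determination coefficient of the OLS fit of ratio on
#'   thickness.
#' @slot slope,intercept the OLS fit coefficients.
#' @slot perImage data.frame of per-image diagnostics (columns scanned,
#'   accepted, rejected) — filled by [runAttenuationAnalysis()].
#' @exportClass AttenuationDataset
setClass("AttenuationDataset",
  representation(
    records = "data.frame",
    nColumns = "integer",
    nPixelsAnalyzed = "integer",
    r = "numeric",
    rSquared = "numeric",
    slope = "numeric",
    intercept = "numeric",
    perImage = "data.frame"
  ),
  prototype(perImage = data.frame())
)

setValidity("AttenuationDataset", function(object) {
  if (object@nColumns != nrow(object@records)) {
    return("nColumns must equal nrow(records)")
  }
  if (is.na(object@r)) { # degenerate fit (e.g. single thickness value)
    return(TRUE)
  }
  if (abs(object@r) > 1 + 1e-12) {
    return("r must lie in [-1, 1]")
  }
  if (object@rSquared < -1e-12 || object@rSquared > 1 + 1e-12) {
    return("rSquared must lie in [0, 1]")
  }
  if (abs(object@rSquared - object@r^2) > 1e-12) {
    return("rSquared must equal r^2 for the simple linear fit")
  }
  TRUE
})

#' MusclePrep: geometry of an isolated muscle preparation
#'
#' Holds what is needed to estimate the cross-sectional area of a muscle
#' strip for specific-force normalisation: wet mass, optimal length L0, the
#' muscle-length to fiber-length ratio (1 for diaphragm strips) and tissue
#' density.
#'
#' @slot mass wet muscle mass in g.
#' @slot l0 optimal length in cm.
#' @slot lengthToFiberRatio dimensionless Lf/L0 factor (diaphragm = 1).
#' @slot density muscle density in g/cm^3 (default 1.06).
#' @exportClass MusclePrep
setClass("MusclePrep",
  representation(
    mass = "numeric", l0 = "numeric",
    lengthToFiberRatio = "numeric", density = "numeric"
  )
)

setValidity("MusclePrep", function(object) {
  vals <- c(object@mass, object@l0, object@lengthToFiberRatio, object@density)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    return("mass, l0, lengthToFiberRatio and density must all be positive")
  }
  TRUE
})

#' Construct a MusclePrep
#'
#' @param mass wet mass in g.
#' @param l0 optimal length in cm.
#' @param lengthToFiberRatio Lf/L0 ratio; 1 for diaphragm strips.
#' @param density muscle density in g/cm^3; 1.06 by convention.
#' @return A [MusclePrep-class] object.
#' @examples
#' musclePrep(mass = 0.0106, l0 = 1) # CSA = 0.01 cm^2
#' @export
musclePrep <- function(mass, l0, lengthToFiberRatio = 1, density = 1.06) {
  new("MusclePrep",
    mass = as.numeric(mass), l0 = as.numeric(l0),
    lengthToFiberRatio = as.numeric(lengthToFiberRatio),
    density = as.numeric(density)
  )
}
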