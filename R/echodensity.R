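## Echodensity: first-order grayscale statistics of an outlined diaphragm
## region on the 8-bit scale, per-animal averaging over repeated frames, and
## group percent differences.

#' Echodensity of a region of interest
#'
#' Computes the grayscale histogram (256 integer bins of width 1) and the
#' mean pixel intensity of the pixels inside the ROI. Echodensity is always
#' computed on the raw 0-255 scale; higher values indicate more echogenic
#' (typically fibrotic or fatty) tissue.
#'
#' The ROI pixel count is checked against `targetPixels` (outlined diaphragm
#' sections are drawn at near-constant size, 4514 pixels by default): a
#' deviation beyond `tolerance` raises a warning, not an error, since hand
#' drawn regions vary by a few pixels.
#'
#' @param frame an [UltrasoundFrame-class] with `scale = "raw_0_255"`.
#' @param roi an [ROI-class] congruent with `frame`.
#' @param targetPixels nominal ROI size in pixels, or `NA` to skip the check.
#' @param tolerance allowed fractional deviation from `targetPixels`
#'   (default 0.02, i.e. two percent).
#' @return An [EchodensityResult-class].
#' @examples
#' f <- UltrasoundFrame(matrix(112, 10, 10))
#' r <- ROI(matrix(TRUE, 10, 10))
#' meanPI(roiEchodensity(f, r, targetPixels = NA))
#' @export
roiEchodensity <- function(frame, roi, targetPixels = 4514, tolerance = 0.02) {
  stopifnot(is(frame, "UltrasoundFrame"), is(roi, "ROI"))
  if (frameScale(frame) != "raw_0_255") {
    stop("echodensity is computed on the raw 0-255 scale")
  }
  if (!identical(dim(framePixels(frame)), dim(roiMask(roi)))) {
    stop("ROI mask is not congruent with the frame")
  }
  px <- framePixels(frame)[roiMask(roi)]
  if (length(px) == 0L) {
    stop("empty ROI")
  }
  if (!is.na(targetPixels) &&
    abs(length(px) - targetPixels) > tolerance * targetPixels) {
    warning(sprintf(
      "ROI has %d pixels; target is %s (+/- %.0f%%)",
      length(px), format(targetPixels), 100 * tolerance
    ))
  }
  bins <- tabulate(as.integer(px) + 1L, nbins = 256L)
  new("EchodensityResult",
    meanPI = mean(px), histogram = as.integer(bins),
    pixelCount = length(px), frameIds = sourceId(frame)
  )
}

#' Per-animal echodensity over repeated frames
#'
#' The per-animal value is the unweighted mean of the per-frame mean pixel
#' intensities, conventionally over 4 frames of the same acquisition with
#' the ROI drawn in the same area; a different frame count triggers a
#' warning. The pooled histogram is retained for plotting.
#'
#' @param results list of [EchodensityResult-class] objects (one per frame).
#' @return An [EchodensityResult-class] whose `meanPI` is the across-frame
#'   mean. Note its `meanPI` is the frame average, not the pooled-pixel mean.
#' @export
animalEchodensity <- function(results) {
  stopifnot(length(results) >= 1L)
  ok <- vapply(results, function(r) is(r, "EchodensityResult"), logical(1L))
  if (!all(ok)) {
    stop("all elements must be EchodensityResult objects")
  }
  if (length(results) != 4L) {
    warning(sprintf(
      "per-animal echodensity conventionally uses 4 frames; got %d",
      length(results)
    ))
  }
  m <- mean(vapply(results, meanPI, numeric(1L)))
  hist <- Reduce(`+`, lapply(results, piHistogram))
  npx <- sum(vapply(results, pixelCount, integer(1L)))
  ## pooled histogram keeps its own (pixel-weighted) mean so the object stays
  ## internally consistent; the reported per-animal value is the unweighted
  ## frame mean `meanPI` of the returned list
  pooled <- new("EchodensityResult",
    meanPI = sum((0:255) * hist) / npx, histogram = as.integer(hist),
    pixelCount = as.integer(npx),
    frameIds = unlist(lapply(results, function(r) r@frameIds))
  )
  structure(list(
    meanPI = m,
    pooled = pooled,
    nFrames = length(results)
  ), class = "animalEchodensity")
}

#' @export
print.animalEchodensity <- function(x, ...) {
  cat(sprintf(
    "Per-animal echodensity: mean P.I. %.2f over %d frames (%d pixels pooled)\n",
    x$meanPI, x$nFrames, pixelCount(x$pooled)
  ))
  invisible(x)
}

#' Percent difference between two group means
#'
#' `100 * (meanB - meanA) / meanA`, with group A as the reference
#' (e.g. wild-type). Reported to one decimal in printed summaries.
#'
#' @param meanA reference group mean (> 0).
#' @param meanB comparison group mean.
#' @return The percent difference (full precision; round to 1 decimal for
#'   reporting).
#' @examples
#' groupPercentDifference(88.40, 112.82) # +27.6
#' @export
groupPercentDifference <- function(meanA, meanB) {
  if (!is.finite(meanA) || meanA <= 0) {
    stop("reference mean must be positive")
  }
  100 * (meanB - meanA) / meanA
}
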