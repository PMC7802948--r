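## Image I/O and preprocessing shared by the echodensity and abdominal-wall
## modules: load, grayscale conversion, normalization, crop, ROI handling.

## BT.709 luminance weights used for RGB(A) -> grayscale collapse. Ultrasound
## exports are gray-on-gray so any constant-weight choice gives the same
## result there; the weight set is kept as a package constant.
.LUMA_WEIGHTS <- c(0.2126, 0.7152, 0.0722)

## round half away from zero (base round() is half-to-even)
.roundHalfUp <- function(x) floor(x + 0.5)

#' Load an ultrasound still frame from PNG or TIFF
#'
#' Reads an 8-bit grayscale, RGB or RGBA image and collapses colour channels
#' to a single grayscale channel with BT.709 luminance weights
#' (0.2126 R + 0.7152 G + 0.0722 B, alpha ignored), rounding half-up to
#' integers on the 0-255 scale.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @param mmPerPixel optional physical pixel pitch (mm) to attach.
#' @return An [UltrasoundFrame-class] with `scale = "raw_0_255"`.
#' @examples
#' p <- tempfile(fileext = ".png")
#' png::writePNG(matrix(runif(64), 8, 8), p)
#' loadFrame(p)
#' @export
loadFrame <- function(path, mmPerPixel = NA_real_) {
  if (!file.exists(path)) {
    stop("cannot read image file: ", path)
  }
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '", ext, "' for file: ", path)
  )
  if (is.list(img)) img <- img[[1L]] # multi-page TIFF: first page
  px <- if (length(dim(img)) == 2L) {
    .roundHalfUp(img * 255)
  } else if (length(dim(img)) == 3L && dim(img)[3L] >= 3L) {
    lum <- .LUMA_WEIGHTS[1L] * img[, , 1L] +
      .LUMA_WEIGHTS[2L] * img[, , 2L] +
      .LUMA_WEIGHTS[3L] * img[, , 3L]
    .roundHalfUp(lum * 255)
  } else if (length(dim(img)) == 3L && dim(img)[3L] %in% c(1L, 2L)) {
    .roundHalfUp(img[, , 1L] * 255) # gray or gray+alpha
  } else {
    stop("unsupported channel layout in file: ", path)
  }
  UltrasoundFrame(px,
    scale = "raw_0_255", mmPerPixel = mmPerPixel,
    sourceId = basename(path)
  )
}

#' Write a frame to an 8-bit grayscale PNG
#'
#' Raw frames round-trip losslessly; normalized frames are quantised to
#' 8 bits on write.
#'
#' @param frame an [UltrasoundFrame-class].
#' @param path output `.png` path.
#' @return `path`, invisibly.
#' @export
writeFrame <- function(frame, path) {
  stopifnot(is(frame, "UltrasoundFrame"))
  px <- framePixels(frame)
  if (frameScale(frame) == "raw_0_255") px <- px / 255
  png::writePNG(px, path)
  invisible(path)
}

#' Normalize a frame to its own maximum
#'
#' Divides every pixel by the frame's maximum intensity, so the brightest
#' pixel becomes exactly 1. This is a per-frame normalization (not a fixed
#' division by 255): the maximum of the output is 1 whenever the input is
#' not all-zero.
#'
#' @param frame an [UltrasoundFrame-class] with `scale = "raw_0_255"`.
#' @return An [UltrasoundFrame-class] with `scale = "normalized_0_1"`.
#' @export
normalizeFrame <- function(frame) {
  stopifnot(is(frame, "UltrasoundFrame"))
  if (frameScale(frame) != "raw_0_255") {
    stop("normalizeFrame() expects a raw 0-255 frame")
  }
  mx <- max(framePixels(frame))
  if (mx <= 0) {
    stop("cannot normalize an all-zero frame")
  }
  UltrasoundFrame(framePixels(frame) / mx,
    scale = "normalized_0_1",
    mmPerPixel = mmPerPixel(frame), sourceId = sourceId(frame)
  )
}

#' Crop a frame to a rectangular sub-grid
#'
#' Bounds are 1-based and inclusive (the R matrix convention): the result
#' holds rows `top:bottom` and columns `left:right` of the input. Row 1 is
#' the top of the image (shallowest depth). `mmPerPixel` is preserved.
#'
#' @param frame an [UltrasoundFrame-class].
#' @param top,bottom,left,right inclusive pixel bounds; defaults select the
#'   full extent along that axis.
#' @return The cropped [UltrasoundFrame-class].
#' @export
cropFrame <- function(frame, top = 1L, bottom = nrow(framePixels(frame)),
                      left = 1L, right = ncol(framePixels(frame))) {
  stopifnot(is(frame, "UltrasoundFrame"))
  px <- framePixels(frame)
  if (top < 1L || left < 1L || bottom > nrow(px) || right > ncol(px)) {
    stop("crop bounds outside the frame")
  }
  if (bottom < top || right < left) {
    stop("crop would produce an empty frame")
  }
  UltrasoundFrame(px[top:bottom, left:right, drop = FALSE],
    scale = frameScale(frame), mmPerPixel = mmPerPixel(frame),
    sourceId = sourceId(frame)
  )
}

#' Load an ROI mask from a PNG image
#'
#' Any pixel with nonzero intensity is inside the region.
#'
#' @param path path to a grayscale PNG mask.
#' @return An [ROI-class].
#' @export
loadROI <- function(path) {
  f <- loadFrame(path)
  ROI(framePixels(f) > 0)
}

#' Rasterize a polygon into an ROI mask (even-odd fill)
#'
#' Vertices are given in pixel coordinates (row, col), 1-based; the polygon
#' is closed implicitly. A pixel is inside when a ray from its centre crosses
#' the polygon boundary an odd number of times.
#'
#' @param vertices two-column matrix or data.frame of (row, col) vertices.
#' @param nrow,ncol dimensions of the target mask.
#' @return An [ROI-class].
#' @examples
#' roiFromPolygon(cbind(c(2, 2, 9, 9), c(2, 9, 9, 2)), 10, 10)
#' @export
roiFromPolygon <- function(vertices, nrow, ncol) {
  v <- as.matrix(vertices)
  if (ncol(v) != 2L || base::nrow(v) < 3L) {
    stop("vertices must be a 2-column matrix with at least 3 rows")
  }
  vr <- v[, 1L]
  vc <- v[, 2L]
  n <- base::nrow(v)
  ## pixel centres
  rr <- rep(seq_len(nrow), times = ncol)
  cc <- rep(seq_len(ncol), each = nrow)
  inside <- logical(length(rr))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vr[i] > rr) != (vr[j] > rr)) &
      (cc < (vc[j] - vc[i]) * (rr - vr[i]) / (vr[j] - vr[i]) + vc[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  ROI(matrix(inside, nrow = nrow, ncol = ncol))
}
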