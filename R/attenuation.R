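## Per-column abdominal-wall (AW) analysis: Gaussian blur + Canny edges on
## the normalized frame, per-column pairing of the band edges under the
## 5-50 px thickness criterion, thickness/intensity metrics, consolidation
## and the ratio-vs-thickness correlation.

## reflect (symmetric) index folding: ... 2 1 | 1 2 ... n | n n-1 ...
.reflectIndex <- function(i, n) {
  j <- (i - 1L) %% (2L * n)
  ifelse(j < n, j + 1L, 2L * n - j)
}

## separable Gaussian convolution with symmetric boundary handling
.gaussSmooth <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  nr <- nrow(m)
  nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (d in -r:r) { # rows
    out <- out + k[d + r + 1L] * m[.reflectIndex(seq_len(nr) + d, nr), , drop = FALSE]
  }
  m2 <- matrix(0, nr, nc)
  for (d in -r:r) { # columns
    m2 <- m2 + k[d + r + 1L] * out[, .reflectIndex(seq_len(nc) + d, nc), drop = FALSE]
  }
  m2
}

## shift a matrix by (dr, dc) with symmetric boundary handling, so that
## gradients at the frame border stay small instead of producing spurious
## border edges
.shiftReflect <- function(m, dr, dc) {
  m[
    .reflectIndex(seq_len(nrow(m)) - dr, nrow(m)),
    .reflectIndex(seq_len(ncol(m)) - dc, ncol(m)),
    drop = FALSE
  ]
}

## shift a matrix by (dr, dc), padding with `fill`
.shiftMat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m)
  nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr) - dr
  cs <- seq_len(nc) - dc
  okr <- rs >= 1L & rs <= nr
  okc <- cs >= 1L & cs <= nc
  out[okr, okc] <- m[rs[okr], cs[okc], drop = FALSE]
  out
}

#' Gaussian blur of a normalized frame
#'
#' Separable Gaussian convolution with symmetric (reflect) boundary
#' handling; the normalized kernel keeps intensities within \[0, 1\].
#'
#' @param frame an [UltrasoundFrame-class] with `scale = "normalized_0_1"`.
#' @param sigma Gaussian standard deviation in pixels (> 0).
#' @return The blurred [UltrasoundFrame-class].
#' @export
blurFrame <- function(frame, sigma) {
  stopifnot(is(frame, "UltrasoundFrame"))
  if (frameScale(frame) != "normalized_0_1") {
    stop("blurFrame() expects a normalized frame")
  }
  if (!is.finite(sigma) || sigma <= 0) {
    stop("sigma must be positive")
  }
  UltrasoundFrame(.gaussSmooth(framePixels(frame), sigma),
    scale = "normalized_0_1", mmPerPixel = mmPerPixel(frame),
    sourceId = sourceId(frame)
  )
}

#' Canny edge detection
#'
#' Classical Canny: Gaussian smoothing, Sobel gradients, non-maximum
#' suppression along the quantised gradient direction, and double-threshold
#' hysteresis linking (8-connectivity). The `low`/`high` thresholds are
#' fractions of the maximum gradient magnitude in the image, which makes
#' the defaults robust to the smoothing scale and to the absolute step
#' height; a constant frame yields no edges.
#'
#' @param frame an [UltrasoundFrame-class] with `scale = "normalized_0_1"`,
#'   or a numeric matrix in \[0, 1\].
#' @param sigma smoothing scale in pixels.
#' @param low,high hysteresis thresholds as fractions of the maximum
#'   gradient magnitude, `0 <= low < high <= 1`.
#' @return A logical matrix congruent with the frame; `TRUE` = edge pixel.
#' @export
cannyEdges <- function(frame, sigma = 2, low = 0.1, high = 0.2) {
  px <- if (is(frame, "UltrasoundFrame")) {
    if (frameScale(frame) != "normalized_0_1") {
      stop("cannyEdges() expects a normalized frame")
    }
    framePixels(frame)
  } else {
    as.matrix(frame)
  }
  if (!(low >= 0 && low < high && high <= 1)) {
    stop("thresholds must satisfy 0 <= low < high <= 1")
  }
  sm <- .gaussSmooth(px, sigma)
  ## Sobel gradients with symmetric boundaries (normalised so a unit step
  ## gives magnitude ~1)
  gx <- (.shiftReflect(sm, 0, -1) - .shiftReflect(sm, 0, 1)) / 2
  gx <- (.shiftReflect(gx, -1, 0) + 2 * gx + .shiftReflect(gx, 1, 0)) / 2
  gy <- (.shiftReflect(sm, -1, 0) - .shiftReflect(sm, 1, 0)) / 2
  gy <- (.shiftReflect(gy, 0, -1) + 2 * gy + .shiftReflect(gy, 0, 1)) / 2
  mag <- sqrt(gx^2 + gy^2)
  mmax <- max(mag)
  if (mmax == 0) {
    return(matrix(FALSE, nrow(px), ncol(px)))
  }
  ## quantise gradient direction into 4 sectors (angle mod 180)
  ang <- atan2(gy, gx) * 180 / pi
  ang <- ang %% 180
  sector <- integer(length(ang))
  sector[(ang >= 22.5 & ang < 67.5)] <- 1L # diagonal r+1,c+1
  sector[(ang >= 67.5 & ang < 112.5)] <- 2L # vertical r+/-1
  sector[(ang >= 112.5 & ang < 157.5)] <- 3L # diagonal r+1,c-1
  sector <- matrix(sector, nrow(px), ncol(px))
  offs <- list(
    `0` = c(0L, 1L), `1` = c(1L, 1L), `2` = c(1L, 0L), `3` = c(1L, -1L)
  )
  eps <- 1e-9 * mmax
  nr <- nrow(px)
  nc <- ncol(px)
  nms <- matrix(0, nr, nc)
  for (s in 0:3) {
    o <- offs[[s + 1L]]
    ## .shiftMat(m, dr, dc)[r, c] = m[r - dr, c - dc], so the neighbor in
    ## the +offset direction is obtained with a negative shift
    nplus <- .shiftMat(mag, -o[1L], -o[2L])
    nminus <- .shiftMat(mag, o[1L], o[2L])
    keep <- sector == s & mag >= nminus - eps & mag > nplus + eps
    idx <- which(keep)
    if (length(idx) == 0L) next
    ## subpixel refinement: a blurred step peaks midway between two pixel
    ## rows, and noise makes the discrete argmax flip between them. Fit a
    ## parabola through the three magnitudes along the gradient direction
    ## and mark the first pixel at or after the interpolated peak, which is
    ## stable under noise well below half a pixel of jitter.
    den <- nminus[idx] - 2 * mag[idx] + nplus[idx]
    delta <- ifelse(den < -eps, 0.5 * (nminus[idx] - nplus[idx]) / den, 0)
    delta <- pmin(0.5, pmax(-0.5, delta))
    shift <- ceiling(delta - 1e-9)
    r0 <- (idx - 1L) %% nr + 1L
    c0 <- (idx - 1L) %/% nr + 1L
    r1 <- r0 + shift * o[1L]
    c1 <- c0 + shift * o[2L]
    ok <- r1 >= 1L & r1 <= nr & c1 >= 1L & c1 <= nc
    tgt <- cbind(r1[ok], c1[ok])
    nms[tgt] <- pmax(nms[tgt], mag[idx[ok]])
  }
  strong <- nms >= high * mmax
  weak <- nms >= low * mmax
  ## hysteresis: grow strong edges through connected weak pixels
  repeat {
    grown <- strong
    for (dr in -1:1) {
      for (dc in -1:1) {
        if (dr == 0L && dc == 0L) next
        grown <- grown | .shiftMat(strong, dr, dc, fill = FALSE)
      }
    }
    grown <- grown & weak
    newstrong <- strong | grown
    if (identical(newstrong, strong)) break
    strong <- newstrong
  }
  strong
}

#' Detect the abdominal-wall band in one pixel column
#'
#' Scans the column top-down over the detected edge rows and returns the
#' first (shallowest) pair of consecutive edge rows whose separation is
#' strictly greater than `minThickness` and strictly less than
#' `maxThickness` pixels, so only unambiguous walls are accepted. The AW is the
#' most superficial bright layer, so deeper qualifying pairs are ignored.
#'
#' @param edges logical edge matrix from [cannyEdges()].
#' @param column column index (1-based).
#' @param minThickness,maxThickness strict thickness bounds in pixels
#'   (defaults 5 and 50).
#' @return `c(top = , bottom = )` edge rows, or `NULL` when no pair
#'   qualifies (a valid outcome, not an error).
#' @export
detectAWBand <- function(edges, column, minThickness = 5L, maxThickness = 50L) {
  stopifnot(is.logical(edges), column >= 1L, column <= ncol(edges))
  rows <- which(edges[, column])
  if (length(rows) < 2L) {
    return(NULL)
  }
  gaps <- diff(rows)
  ok <- which(gaps > minThickness & gaps < maxThickness)
  if (length(ok) == 0L) {
    return(NULL)
  }
  i <- ok[1L]
  c(top = rows[i], bottom = rows[i + 1L])
}

#' Thickness and intensity metrics for one column
#'
#' Given the detected band `(top, bottom)` in a column of the normalized
#' (unblurred) frame: thickness is `bottom - top` pixels; the AW mean pixel
#' intensity averages the half-open row range `[top, bottom)`; the below-AW
#' intensity averages the `belowWindow` (50 by default) pixels immediately
#' under the band, rows `[bottom, bottom + belowWindow)`; the ratio is
#' below/AW.
#'
#' @param frame normalized [UltrasoundFrame-class] (the un-blurred pixels
#'   the metrics are read from).
#' @param column column index.
#' @param band `c(top, bottom)` as returned by [detectAWBand()].
#' @param belowWindow pixels averaged under the band (default 50).
#' @param imageId identifier copied into the record.
#' @return A one-row data.frame (image_id, column, top_edge_row,
#'   bottom_edge_row, aw_thickness, aw_mean_pi, below_aw_pi, ratio), or
#'   `NULL` when fewer than `belowWindow` pixels remain below the band
#'   (the column is discarded).
#' @export
columnMetrics <- function(frame, column, band, belowWindow = 50L,
                          imageId = sourceId(frame)) {
  stopifnot(is(frame, "UltrasoundFrame"))
  px <- framePixels(frame)
  top <- band[[1L]]
  bottom <- band[[2L]]
  stopifnot(top < bottom)
  if (bottom + belowWindow - 1L > nrow(px)) {
    return(NULL)
  }
  awMean <- mean(px[top:(bottom - 1L), column])
  below <- mean(px[bottom:(bottom + belowWindow - 1L), column])
  data.frame(
    image_id = imageId, column = as.integer(column),
    top_edge_row = as.integer(top), bottom_edge_row = as.integer(bottom),
    aw_thickness = as.integer(bottom - top),
    aw_mean_pi = awMean, below_aw_pi = below,
    ratio = below / awMean,
    stringsAsFactors = FALSE
  )
}

#' Consolidate per-column records and fit ratio against thickness
#'
#' Pools records from all images into one data frame, computes the Pearson
#' correlation `r` between AW thickness and the below/AW intensity ratio,
#' and the determination coefficient of the ordinary least-squares fit of
#' ratio on thickness (for the simple linear fit, `R^2 = r^2`).
#'
#' @param records data.frame of rows from [columnMetrics()] (or a list of
#'   such data.frames).
#' @param belowWindow below-AW window used, for the pixels-analyzed count.
#' @return An [AttenuationDataset-class].
#' @export
consolidateRecords <- function(records, belowWindow = 50L) {
  if (is.list(records) && !is.data.frame(records)) {
    records <- do.call(rbind, records)
  }
  if (is.null(records) || nrow(records) < 2L) {
    stop("need at least 2 per-column records")
  }
  if (length(unique(records$aw_thickness)) < 2L) {
    stop("thickness has zero variance; correlation undefined")
  }
  if (stats::var(records$ratio) == 0) {
    stop("ratio has zero variance; correlation undefined")
  }
  r <- stats::cor(records$aw_thickness, records$ratio)
  fit <- stats::lm(ratio ~ aw_thickness, data = records)
  r2 <- summary(fit)$r.squared
  new("AttenuationDataset",
    records = records, nColumns = nrow(records),
    nPixelsAnalyzed = as.integer(sum(records$aw_thickness + belowWindow)),
    r = r, rSquared = r2,
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L])
  )
}

#' Run the full abdominal-wall attenuation analysis
#'
#' For each image: normalize (raw frames only), Gaussian blur, Canny edge
#' detection, then scan every pixel column for the AW band and compute the
#' thickness/intensity metrics from the normalized un-blurred pixels;
#' finally consolidate all columns and fit the below/AW ratio against
#' thickness. Columns with no qualifying edge pair or with fewer than
#' `belowWindow` pixels under the band are excluded and counted in the
#' per-image report.
#'
#' @param images character vector of PNG/TIFF paths, or a list of
#'   [UltrasoundFrame-class] objects.
#' @param blurSigma preliminary Gaussian blur scale (pixels).
#' @param cannySigma smoothing scale inside the Canny detector.
#' @param low,high Canny hysteresis thresholds (fractions of the maximum
#'   gradient magnitude).
#' @param minThickness,maxThickness strict AW-thickness acceptance bounds
#'   (pixels).
#' @param belowWindow pixels averaged below the band.
#' @return An [AttenuationDataset-class] with the per-image report in its
#'   `perImage` slot.
#' @examples
#' frames <- simulateBModeSet(c(12, 20, 28), height = 120, width = 30,
#'                            attenuationSlope = -0.01, speckleCV = 0.03)
#' runAttenuationAnalysis(frames)
#' @export
runAttenuationAnalysis <- function(images, blurSigma = 1, cannySigma = 2,
                                   low = 0.1, high = 0.2,
                                   minThickness = 5L, maxThickness = 50L,
                                   belowWindow = 50L) {
  if (length(images) == 0L) {
    stop("no images supplied")
  }
  frames <- if (is.character(images)) lapply(images, loadFrame) else images
  allRec <- list()
  report <- list()
  for (f in frames) {
    stopifnot(is(f, "UltrasoundFrame"))
    if (frameScale(f) == "raw_0_255") f <- normalizeFrame(f)
    blurred <- blurFrame(f, blurSigma)
    edges <- cannyEdges(blurred, sigma = cannySigma, low = low, high = high)
    nc <- ncol(edges)
    recs <- vector("list", nc)
    nNoBand <- 0L
    nNoRoom <- 0L
    for (col in seq_len(nc)) {
      band <- detectAWBand(edges, col, minThickness, maxThickness)
      if (is.null(band)) {
        nNoBand <- nNoBand + 1L
        next
      }
      rec <- columnMetrics(f, col, band, belowWindow = belowWindow)
      if (is.null(rec)) {
        nNoRoom <- nNoRoom + 1L
        next
      }
      recs[[col]] <- rec
    }
    recs <- do.call(rbind, recs)
    allRec[[length(allRec) + 1L]] <- recs
    report[[length(report) + 1L]] <- data.frame(
      image_id = sourceId(f), columns_scanned = nc,
      columns_accepted = if (is.null(recs)) 0L else nrow(recs),
      no_qualifying_pair = nNoBand, insufficient_depth = nNoRoom,
      stringsAsFactors = FALSE
    )
  }
  records <- do.call(rbind, allRec)
  if (is.null(records) || nrow(records) == 0L) {
    stop("no qualifying columns found in any image; check blur/threshold settings")
  }
  ds <- if (length(unique(records$aw_thickness)) < 2L ||
    stats::var(records$ratio) == 0) {
    warning("thickness or ratio has zero variance; correlation undefined (r = NA)")
    new("AttenuationDataset",
      records = records, nColumns = nrow(records),
      nPixelsAnalyzed = as.integer(sum(records$aw_thickness + belowWindow)),
      r = NA_real_, rSquared = NA_real_, slope = NA_real_,
      intercept = NA_real_
    )
  } else {
    consolidateRecords(records, belowWindow = belowWindow)
  }
  ds@perImage <- do.call(rbind, report)
  ds
}

#' Scatter plot of the below/AW ratio against AW thickness
#'
#' One point per accepted column, with the ordinary least-squares fit line
#' and the correlation annotated.
#'
#' @param ds an [AttenuationDataset-class].
#' @param ... further arguments to [graphics::plot()].
#' @return `ds`, invisibly.
#' @export
plotAttenuation <- function(ds, ...) {
  stopifnot(is(ds, "AttenuationDataset"))
  rec <- awRecords(ds)
  graphics::plot(rec$aw_thickness, rec$ratio,
    xlab = "AW thickness (pixels)", ylab = "Below-AW P.I. / AW P.I.",
    pch = 16, col = grDevices::adjustcolor("steelblue", 0.5), ...
  )
  graphics::abline(ds@intercept, ds@slope, col = "firebrick", lwd = 2)
  graphics::mtext(
    sprintf("r = %.4f, R^2 = %.5f, n = %d", ds@r, ds@rSquared, nColumns(ds)),
    side = 3, line = 0.2, cex = 0.8
  )
  invisible(ds)
}

#' Diagnostic plot of one pixel column
#'
#' Plots the normalized intensity profile of a single column against depth,
#' together with its moving average (10 samples by default). Purely a
#' visual aid for checking the band geometry; the moving average plays no
#' role in the metrics.
#'
#' @param frame a normalized [UltrasoundFrame-class].
#' @param column column index.
#' @param window moving-average window in samples.
#' @return The moving-average vector, invisibly.
#' @export
columnProfilePlot <- function(frame, column, window = 10L) {
  stopifnot(is(frame, "UltrasoundFrame"))
  prof <- framePixels(frame)[, column]
  ma <- as.numeric(stats::filter(prof, rep(1 / window, window), sides = 1))
  graphics::plot(prof,
    type = "l", col = "grey50",
    xlab = "depth (pixels)", ylab = "normalized P.I.",
    main = sprintf("column %d", column)
  )
  graphics::lines(ma, col = "firebrick", lwd = 2)
  invisible(ma)
}

#' Seeded replicate study of attenuation-slope recovery
#'
#' Convenience wrapper used for validation: for each replicate, simulate a
#' multi-thickness phantom set with the given attenuation slope and speckle,
#' run the full per-column analysis and record the fitted correlation.
#'
#' @param nReplicates number of seeded replicates.
#' @param slope ground-truth attenuation slope (see [bmodeTruth()]).
#' @param thicknesses AW thicknesses (pixels), one frame per value and
#'   replicate.
#' @param height,width phantom dimensions.
#' @param speckleCV speckle coefficient of variation.
#' @param seed base seed; replicate k uses `seed + 1000 * k` for its set.
#' @param ... further arguments to [runAttenuationAnalysis()].
#' @return data.frame with one row per replicate: replicate, r, r_squared,
#'   n_columns.
#' @export
attenuationSimStudy <- function(nReplicates = 20L, slope = 0,
                                thicknesses = rep(seq(8L, 40L, by = 4L), 2L),
                                height = 120L, width = 32L,
                                speckleCV = 0.05, seed = 1L, ...) {
  rows <- lapply(seq_len(nReplicates), function(k) {
    frames <- simulateBModeSet(
      thicknesses,
      height = height, width = width,
      seed = seed + 1000L * k, attenuationSlope = slope,
      speckleCV = speckleCV
    )
    ds <- runAttenuationAnalysis(frames, ...)
    data.frame(
      replicate = k, r = attenuationR(ds), r_squared = attenuationR2(ds),
      n_columns = nColumns(ds)
    )
  })
  do.call(rbind, rows)
}
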