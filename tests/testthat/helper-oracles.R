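# Independent brute-force oracles, kept deliberately naive (explicit loops,
# no shared code with the implementation paths they check).

# scan one column's edge rows for the first consecutive pair with a gap
# strictly inside (minT, maxT)
oracleBandDetect <- function(edgeColumn, minT = 5L, maxT = 50L) {
  rows <- c()
  for (r in seq_along(edgeColumn)) {
    if (isTRUE(edgeColumn[r])) rows <- c(rows, r)
  }
  if (length(rows) < 2L) {
    return(NULL)
  }
  for (i in seq_len(length(rows) - 1L)) {
    gap <- rows[i + 1L] - rows[i]
    if (gap > minT && gap < maxT) {
      return(c(top = rows[i], bottom = rows[i + 1L]))
    }
  }
  NULL
}

# per-column metrics by explicit summation
oracleColumnMetrics <- function(px, column, top, bottom, window = 50L) {
  if (bottom + window - 1L > nrow(px)) {
    return(NULL)
  }
  s <- 0
  for (r in top:(bottom - 1L)) s <- s + px[r, column]
  aw <- s / (bottom - top)
  s <- 0
  for (r in bottom:(bottom + window - 1L)) s <- s + px[r, column]
  below <- s / window
  list(
    thickness = bottom - top, aw = aw, below = below, ratio = below / aw
  )
}

# brute-force per-column pipeline over a whole edge grid + frame
oracleAllColumns <- function(px, edges, minT = 5L, maxT = 50L, window = 50L) {
  out <- list()
  for (col in seq_len(ncol(edges))) {
    band <- oracleBandDetect(edges[, col], minT, maxT)
    if (is.null(band)) next
    m <- oracleColumnMetrics(px, col, band[["top"]], band[["bottom"]], window)
    if (is.null(m)) next
    out[[length(out) + 1L]] <- data.frame(
      column = col, top = band[["top"]], bottom = band[["bottom"]],
      thickness = m$thickness, aw = m$aw, below = m$below, ratio = m$ratio
    )
  }
  if (length(out)) do.call(rbind, out) else NULL
}

# write a small RGBA PNG with constant channels (0-255 values)
writeRgbaPng <- function(path, r, g, b, a = 255, nrow = 6, ncol = 6) {
  arr <- array(0, dim = c(nrow, ncol, 4))
  arr[, , 1] <- r / 255
  arr[, , 2] <- g / 255
  arr[, , 3] <- b / 255
  arr[, , 4] <- a / 255
  png::writePNG(arr, path)
  path
}

# noise-free multi-breath trace built by explicit concatenation
makeBreathTrace <- function(amplitudes, baseline = 0, sampleRate = 100,
                            inspSamples = 21L, restSamples = 40L) {
  pos <- c()
  for (a in amplitudes) {
    insp <- a * sin(pi * seq(0, 1, length.out = inspSamples))
    pos <- c(pos, baseline + insp, rep(baseline, restSamples))
  }
  MModeTrace((seq_along(pos) - 1L) / sampleRate, pos, sampleRate)
}
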