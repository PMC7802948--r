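normFrame <- function(px) UltrasoundFrame(px, scale = "normalized_0_1")

test_that("Gaussian blur preserves constants, mass and the intensity range", {
  const <- normFrame(matrix(0.42, 15, 15))
  expect_equal(framePixels(blurFrame(const, 2)), matrix(0.42, 15, 15))
  # single interior bright pixel: kernel mass conserved under reflect padding
  px <- matrix(0, 21, 21)
  px[11, 11] <- 1
  bl <- framePixels(blurFrame(normFrame(px), 1))
  expect_equal(sum(bl), 1, tolerance = 1e-6)
  expect_true(all(bl >= 0 & bl <= 1))
  # large sigma drives the frame toward its mean
  set.seed(5)
  rnd <- matrix(runif(400), 20, 20)
  bl2 <- framePixels(blurFrame(normFrame(rnd), 50))
  expect_lt(max(abs(bl2 - mean(rnd))), 0.05)
  expect_error(blurFrame(const, 0), "sigma")
  expect_error(blurFrame(UltrasoundFrame(matrix(1, 3, 3)), 1), "normalized")
})

test_that("Canny finds a sharp step as one contiguous edge row and nothing on constants", {
  expect_false(any(cannyEdges(normFrame(matrix(0.7, 20, 20)))))
  step <- matrix(0.1, 20, 20)
  step[11:20, ] <- 0.9 # height 0.8 at the row 10|11 boundary
  e <- cannyEdges(normFrame(step), sigma = 1.5, low = 0.1, high = 0.2)
  expect_true(all(colSums(e) == 1))
  expect_true(all(which(e, arr.ind = TRUE)[, "row"] == 11))
  expect_error(cannyEdges(normFrame(step), low = 0.5, high = 0.2), "thresholds")
})

test_that("a bright band yields exactly two edge rows per column", {
  px <- matrix(0.2, 60, 24)
  px[21:32, ] <- 0.85 # thickness 12
  e <- cannyEdges(normFrame(px), sigma = 2)
  expect_true(all(colSums(e) == 2))
  rows <- apply(e, 2, which)
  expect_true(all(rows[1, ] == 21 & rows[2, ] == 33))
})

test_that("band pairing follows the strict 5-50 px first-qualifying rule", {
  mkEdges <- function(rows, nrow = 100) {
    m <- matrix(FALSE, nrow, 1)
    m[rows, 1] <- TRUE
    m
  }
  expect_equal(detectAWBand(mkEdges(c(10, 30)), 1), c(top = 10, bottom = 30))
  expect_null(detectAWBand(mkEdges(c(10, 12)), 1)) # gap 2 <= 5
  expect_null(detectAWBand(mkEdges(c(10, 15)), 1)) # gap 5: strict bound
  expect_null(detectAWBand(mkEdges(c(10, 60)), 1)) # gap 50: strict bound
  # first gap 55 fails <50, next gap 15 qualifies
  expect_equal(detectAWBand(mkEdges(c(5, 60, 75)), 1), c(top = 60, bottom = 75))
  expect_null(detectAWBand(mkEdges(7), 1))
  # random edge grids agree with the brute-force scan
  set.seed(31)
  for (i in 1:50) {
    rows <- sort(sample(1:100, sample(0:8, 1)))
    got <- detectAWBand(mkEdges(rows), 1)
    want <- oracleBandDetect(as.logical(mkEdges(rows)))
    if (is.null(want)) expect_null(got) else expect_equal(got, want)
  }
})

test_that("column metrics match direct summation and respect the depth guard", {
  set.seed(13)
  px <- matrix(runif(120 * 5, 0.05, 1), 120, 5)
  f <- normFrame(px)
  rec <- columnMetrics(f, 3, c(top = 10, bottom = 30), imageId = "x")
  want <- oracleColumnMetrics(px, 3, 10, 30)
  expect_equal(rec$aw_thickness, want$thickness)
  expect_equal(rec$aw_mean_pi, want$aw)
  expect_equal(rec$below_aw_pi, want$below)
  expect_equal(rec$ratio, want$ratio)
  # all-1 band over all-0.5 below
  px2 <- matrix(0.5, 100, 2)
  px2[10:29, ] <- 1
  r2 <- columnMetrics(normFrame(px2), 1, c(10, 30))
  expect_equal(r2$ratio, 0.5)
  expect_equal(r2$aw_thickness, 20L)
  # fewer than 50 pixels below the band -> record discarded
  expect_null(columnMetrics(f, 1, c(top = 60, bottom = 80)))
})

test_that("ratio is invariant to global intensity rescaling", {
  set.seed(17)
  px <- matrix(runif(100 * 4, 0.2, 1), 100, 4)
  a <- columnMetrics(normFrame(px), 2, c(12, 31))
  b <- columnMetrics(normFrame(px * 0.5), 2, c(12, 31))
  expect_equal(b$ratio, a$ratio, tolerance = 1e-12)
})

test_that("consolidation fits ratio on thickness with R^2 = r^2", {
  rec <- data.frame(
    image_id = "a", column = 1:20, top_edge_row = 10L,
    bottom_edge_row = 10L + rep(c(10L, 20L, 30L, 40L), 5)
  )
  rec$aw_thickness <- rec$bottom_edge_row - rec$top_edge_row
  rec$aw_mean_pi <- 0.9
  rec$ratio <- 1 - 0.01 * rec$aw_thickness # exactly collinear
  rec$below_aw_pi <- rec$ratio * 0.9
  ds <- suppressWarnings(consolidateRecords(rec)) # lm warns on a perfect fit
  expect_equal(attenuationR(ds), -1)
  expect_equal(attenuationR2(ds), 1)
  expect_equal(ds@slope, -0.01)
  expect_equal(nPixelsAnalyzed(ds), sum(rec$aw_thickness + 50L))
  # ratio independent of thickness: |r| consistent with 0 at n = 500
  set.seed(23)
  null <- rec[rep(1:20, 25), ]
  null$ratio <- sample(null$ratio)
  dn <- consolidateRecords(null)
  expect_lt(abs(attenuationR(dn)), 0.1)
  expect_equal(attenuationR2(dn), attenuationR(dn)^2, tolerance = 1e-12)
  # degenerate inputs
  expect_error(consolidateRecords(rec[1, ]), "2")
  same <- rec
  same$aw_thickness <- 20L
  expect_error(consolidateRecords(same), "zero variance")
})

test_that("the end-to-end pipeline recovers noise-free geometry and reports exclusions", {
  f <- simulateBMode(
    bmodeTruth(awTopRow = 16, awThickness = 20, speckleCV = 0),
    height = 120, width = 25
  )
  ds <- suppressWarnings(runAttenuationAnalysis(list(f)))
  rec <- awRecords(ds)
  expect_equal(nrow(rec), 25L)
  expect_true(all(rec$aw_thickness == 20L))
  expect_true(all(rec$aw_mean_pi == 0.9))
  expect_true(all(rec$below_aw_pi == 0.35))
  expect_true(is.na(attenuationR(ds))) # single thickness: r undefined
  expect_equal(ds@perImage$columns_accepted, 25L)
  expect_error(runAttenuationAnalysis(list()), "no images")
  # internal consistency: pixels = sum over columns of thickness + window
  fr <- simulateBModeSet(c(12, 24), 120, 10, speckleCV = 0)
  ds2 <- suppressWarnings(runAttenuationAnalysis(fr)) # noise-free: perfect fit
  expect_equal(
    nPixelsAnalyzed(ds2),
    sum(awRecords(ds2)$aw_thickness + 50L)
  )
  expect_true(all(awRecords(ds2)$aw_thickness > 5 & awRecords(ds2)$aw_thickness < 50))
})

test_that("per-column pipeline equals the brute-force oracle on small frames", {
  # <= 30x30 fixtures, below-window shortened so the geometry fits
  set.seed(41)
  for (thk in c(7L, 10L, 14L)) {
    tr <- bmodeTruth(
      awTopRow = 4L, awThickness = thk, speckleCV = 0.08,
      seed = 50 + thk
    )
    f <- simulateBMode(tr, height = 30, width = 30, belowWindow = 10L)
    blurred <- blurFrame(f, 1)
    edges <- cannyEdges(blurred, sigma = 1.5)
    got <- suppressWarnings(runAttenuationAnalysis(
      list(f),
      blurSigma = 1, cannySigma = 1.5, belowWindow = 10L
    ))
    want <- oracleAllColumns(framePixels(f), edges, window = 10L)
    rec <- awRecords(got)
    expect_equal(nrow(rec), nrow(want))
    expect_identical(rec$column, want$column)
    expect_identical(rec$top_edge_row, as.integer(want$top))
    expect_identical(rec$bottom_edge_row, as.integer(want$bottom))
    expect_identical(rec$aw_thickness, as.integer(want$thickness))
    expect_equal(rec$aw_mean_pi, want$aw, tolerance = 1e-12)
    expect_equal(rec$below_aw_pi, want$below, tolerance = 1e-12)
    expect_equal(rec$ratio, want$ratio, tolerance = 1e-12)
  }
})
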