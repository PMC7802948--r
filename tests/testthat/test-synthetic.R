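test_that("noise-free B-mode phantoms reproduce their ground truth exactly", {
  tr <- bmodeTruth(
    awTopRow = 16, awThickness = 20, awIntensity = 0.9,
    belowBaseIntensity = 0.35, attenuationSlope = 0, speckleCV = 0
  )
  f <- simulateBMode(tr, height = 120, width = 30)
  px <- framePixels(f)
  expect_true(all(px[16:35, ] == 0.9))
  expect_true(all(px[36:120, ] == 0.35)) # slope 0: below = base everywhere
  expect_true(all(px[1:15, ] == 0.35))
  # nonzero slope shifts the below-band expectation by slope * thk * awI
  tr2 <- bmodeTruth(
    awThickness = 10, awIntensity = 0.8, belowBaseIntensity = 0.4,
    attenuationSlope = -0.02, speckleCV = 0
  )
  f2 <- simulateBMode(tr2, height = 100, width = 10)
  expect_equal(unique(as.vector(framePixels(f2)[26:100, ])), 0.4 - 0.02 * 10 * 0.8)
})

test_that("B-mode geometry without room for the below-window is rejected", {
  expect_error(
    simulateBMode(bmodeTruth(awTopRow = 10, awThickness = 20), 70, 10),
    "below"
  )
})

test_that("speckle has the stated distribution and fixed seeds are bit-identical", {
  # awIntensity 0.5 keeps 1 + cv*z far from the clamp, so band pixels are
  # plain Gaussian with mean 0.5 and sd cv*0.5
  tr <- function(s) {
    bmodeTruth(
      awTopRow = 11, awThickness = 20, awIntensity = 0.5,
      speckleCV = 0.1, seed = s
    )
  }
  band <- unlist(lapply(1:10, function(s) {
    framePixels(simulateBMode(tr(s), height = 90, width = 30))[11:30, ]
  }))
  se <- 0.1 * 0.5 / sqrt(length(band))
  expect_lt(abs(mean(band) - 0.5), 3 * se)
  expect_equal(sd(band), 0.05, tolerance = 0.05)
  expect_identical(
    framePixels(simulateBMode(tr(7), 90, 30)),
    framePixels(simulateBMode(tr(7), 90, 30))
  )
})

test_that("M-mode traces hit their amplitude, baseline and determinism", {
  t0 <- mmodeTruth(amplitudeMm = 1.2, noiseSdMm = 0, baselineMm = 2)
  tr <- simulateMMode(t0, sampleRate = 200)
  expect_equal(max(tracePosition(tr)) - 2, 1.2)
  expect_equal(min(tracePosition(tr)), 2)
  flat <- simulateMMode(mmodeTruth(amplitudeMm = 0, noiseSdMm = 0), 200)
  expect_true(all(tracePosition(flat) == 0))
  n1 <- simulateMMode(mmodeTruth(seed = 3), 200)
  n2 <- simulateMMode(mmodeTruth(seed = 3), 200)
  expect_identical(tracePosition(n1), tracePosition(n2))
  expect_error(simulateMMode(t0, sampleRate = 20), "sample rate")
  expect_error(simulateMMode(t0, sampleRate = 200, duration = 0.5), "duration")
})

test_that("cohorts honour their group means, SDs and correlation", {
  spec0 <- cohortSpec(
    list(
      wt = list(n = 5, mean = c(amp = 0.61, dist = 430), sd = c(amp = 0, dist = 0)),
      mdx = list(n = 5, mean = c(amp = 0.37, dist = 269), sd = c(amp = 0, dist = 0))
    ),
    correlation = 0, seed = 1
  )
  ch <- simulateCohort(spec0)
  expect_equal(nrow(ch), 10)
  expect_true(all(ch$amp[ch$group == "wt"] == 0.61))
  expect_true(all(ch$dist[ch$group == "mdx"] == 269))
  # degenerate correlation 1 -> sample r is 1 up to float tolerance
  spec1 <- cohortSpec(
    list(g = list(n = 30, mean = c(a = 0, b = 10), sd = c(a = 1, b = 2))),
    correlation = 1, seed = 2
  )
  ch1 <- simulateCohort(spec1)
  expect_equal(cor(ch1$a, ch1$b), 1, tolerance = 1e-6)
  expect_identical(simulateCohort(spec1), simulateCohort(spec1))
})

test_that("invalid cohort specifications are rejected", {
  expect_error(
    cohortSpec(list(g = list(n = 1, mean = c(a = 1), sd = c(a = 0)))),
    "n"
  )
  expect_error(
    cohortSpec(
      list(g = list(n = 5, mean = c(a = 1, b = 2, c = 3), sd = c(a = 1, b = 1, c = 1))),
      correlation = -0.9
    ),
    "positive semi-definite"
  )
})

test_that("attenuation slope magnitude strictly strengthens the fitted correlation", {
  # slopes kept shallow enough that the below-band intensity never clamps
  # at zero (which would flatten, not strengthen, the linear correlation)
  slopes <- c(0, -0.002, -0.008)
  rmag <- vapply(slopes, function(s) {
    st <- attenuationSimStudy(3, slope = s, seed = 42)
    mean(abs(st$r))
  }, numeric(1))
  expect_true(all(diff(rmag) > 0))
})
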