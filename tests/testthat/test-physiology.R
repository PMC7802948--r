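test_that("cross-sectional area follows mass over fiber length times density", {
  expect_equal(crossSectionalArea(musclePrep(mass = 0.0106, l0 = 1)), 0.01)
  p1 <- musclePrep(mass = 0.0106, l0 = 1)
  p2 <- musclePrep(mass = 0.0212, l0 = 1)
  expect_equal(crossSectionalArea(p2), 2 * crossSectionalArea(p1))
  set.seed(8)
  for (i in 1:10) {
    m <- runif(1, 0.005, 0.03)
    l <- runif(1, 0.5, 1.5)
    r <- runif(1, 0.7, 1)
    d <- 1.06
    expect_equal(
      crossSectionalArea(musclePrep(m, l, r, d)),
      m / (l * r * d)
    )
  }
  expect_error(musclePrep(-1, 1), "positive")
})

test_that("specific force converts N/cm^2 to kN/m^2", {
  expect_equal(specificForce(0.5, 0.01), 500)
  expect_equal(specificForce(0, 0.02), 0)
  expect_equal(specificForce(0.5, 0.005), 1000) # halving CSA doubles sP
  expect_error(specificForce(-0.1, 0.01), "non-negative")
  expect_error(specificForce(0.1, 0), "positive")
  # linearity through the twitch mean
  set.seed(14)
  f <- runif(5, 0.1, 0.4)
  csa <- 0.013
  expect_equal(
    specificForce(meanTwitch(f * 3), csa),
    3 * specificForce(meanTwitch(f), csa)
  )
})

test_that("twitch averaging is a plain mean with the 5-twitch convention", {
  expect_equal(meanTwitch(rep(7.5, 5)), 7.5)
  expect_equal(meanTwitch(c(8, 9, 10, 11, 12)), 10)
  expect_warning(meanTwitch(c(1, 2, 3)), "5 twitches")
  set.seed(15)
  v <- runif(5)
  expect_equal(meanTwitch(v), sum(v) / 5)
})

test_that("eccentric decay reads pulses 5 and 10 against pulse 1", {
  expect_equal(
    eccentricDecay(c(100, 95, 88, 80, 70, 66, 62, 58, 54, 50)),
    c(decay5 = 30, decay10 = 50)
  )
  expect_equal(unname(eccentricDecay(rep(80, 10))), c(0, 0))
  expect_error(eccentricDecay(c(100, 90)), "1..10")
  expect_error(eccentricDecay(c(0, rep(1, 9))), "positive")
  # unit invariance and oracle arithmetic on random decaying series
  set.seed(16)
  for (i in 1:10) {
    f <- sort(runif(10, 10, 100), decreasing = TRUE)
    d <- eccentricDecay(f)
    expect_equal(unname(d["decay5"]), 100 * (f[1] - f[5]) / f[1])
    expect_equal(unname(d["decay10"]), 100 * (f[1] - f[10]) / f[1])
    expect_equal(eccentricDecay(f * 9.81), d) # mN vs other units
    expect_lte(max(d), 100)
  }
})

test_that("recovery percentages are relative to the pre-protocol tetanus", {
  expect_equal(forceRecovery(120, 120, 120), c(rec4 = 100, rec30 = 100))
  expect_equal(unname(forceRecovery(120, 90, 110)["rec4"]), 75)
  expect_error(forceRecovery(0, 1, 1), "positive")
  set.seed(18)
  pre <- runif(1, 50, 150)
  a <- runif(1, 0, pre)
  b <- runif(1, 0, pre)
  r <- forceRecovery(pre, a, b)
  expect_equal(unname(r), 100 * c(a, b) / pre)
  expect_equal(forceRecovery(pre * 2, a * 2, b * 2), r) # unit invariance
  expect_true(all(r >= 0))
})

test_that("stiffness is the stretch-induced force difference per reference volume", {
  expect_equal(muscleStiffness(100, 100, 12), 0)
  expect_equal(muscleStiffness(130, 100, 10), 3)
  expect_error(muscleStiffness(1, 1, 0), "positive")
  # vectorised over the 10 eccentric stimuli
  after <- c(150, 148, 147, 145, 140, 138, 137, 136, 135, 134)
  before <- c(100, 99, 97, 96, 92, 91, 90, 90, 89, 88)
  v <- 11.3
  expect_equal(muscleStiffness(after, before, v), (after - before) / v)
  # default reference volume is mass/density in mm^3
  expect_equal(defaultStiffnessVolume(musclePrep(0.0106, 1)), 10)
})

test_that("percent change matches the printed longitudinal deltas", {
  expect_equal(round(percentChange(0.139, 0.123), 1), -11.5)
  expect_equal(round(percentChange(269, 183), 1), -32.0)
  expect_equal(percentChange(5, 5), 0)
  expect_error(percentChange(0, 1), "nonzero")
})

test_that("group percent change supports means and per-animal modes", {
  m3 <- c(100, 200, 300)
  m6 <- c(110, 190, 330)
  expect_equal(groupPercentChange(m3, m6), percentChange(200, 210))
  expect_equal(
    groupPercentChange(m3, m6, mode = "per_animal"),
    mean(c(10, -5, 10))
  )
  expect_error(groupPercentChange(1:3, 1:4, mode = "per_animal"), "paired")
  # the two modes agree when baselines are equal
  expect_equal(
    groupPercentChange(rep(100, 4), c(90, 95, 105, 110)),
    groupPercentChange(rep(100, 4), c(90, 95, 105, 110), mode = "per_animal")
  )
})
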