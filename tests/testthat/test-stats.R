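test_that("two-group ANOVA reduces to the squared pooled t statistic", {
  set.seed(51)
  for (i in 1:10) {
    a <- rnorm(sample(4:12, 1))
    b <- rnorm(sample(4:12, 1), mean = runif(1, 0, 2))
    an <- oneWayAnova(list(a = a, b = b))
    tt <- unpairedT(a, b)
    expect_equal(an$F, tt$t^2, tolerance = 1e-10)
    expect_equal(an$p, tt$p, tolerance = 1e-10)
  }
})

test_that("degenerate ANOVA inputs are handled, not propagated as NaN", {
  same <- list(a = c(1, 2, 3), b = c(1, 2, 3))
  an <- oneWayAnova(same)
  expect_equal(an$F, 0)
  expect_equal(an$p, 1)
  const <- list(a = rep(2, 4), b = rep(2, 4))
  an2 <- oneWayAnova(const)
  expect_equal(an2$F, 0)
  expect_equal(an2$p, 1)
  apart <- list(a = rep(1, 4), b = rep(2, 4)) # zero within, nonzero between
  an3 <- oneWayAnova(apart)
  expect_equal(an3$p, 0)
  expect_error(oneWayAnova(list(a = 1:3)), "2")
})

test_that("ANOVA accepts a long-format data.frame and reports the design", {
  df <- data.frame(
    value = c(1, 2, 3, 7, 8, 9, 4, 5, 6),
    group = rep(c("wt", "mdx", "het"), each = 3)
  )
  an <- oneWayAnova(df, posthoc = TRUE)
  expect_equal(an$df, c(2L, 6L))
  expect_equal(sort(an$n), c(3L, 3L, 3L))
  expect_equal(nrow(an$pairwise), 3L)
})

test_that("Bonferroni adjustment caps at one and is monotone in the raw p", {
  set.seed(52)
  g <- list(a = rnorm(8), b = rnorm(8, 0.5), c = rnorm(8, 1), d = rnorm(8, 5))
  pw <- bonferroniPairwise(g)
  expect_equal(nrow(pw), 6L)
  expect_equal(pw$p_adj, pmin(1, pw$p_raw * 6))
  expect_true(all(pw$p_adj <= 1 & pw$p_adj >= pw$p_raw))
  ord <- order(pw$p_raw)
  expect_true(all(diff(pw$p_adj[ord]) >= 0))
  # m = 1: adjusted equals raw
  pw2 <- bonferroniPairwise(list(a = rnorm(6), b = rnorm(6)))
  expect_equal(pw2$p_adj, pw2$p_raw)
  # pooled-variance pairwise t agrees with an independent recomputation
  y <- unlist(g)
  lab <- rep(names(g), each = 8)
  msw <- sum(vapply(g, function(v) sum((v - mean(v))^2), 0)) / (32 - 4)
  tstat <- (mean(g$a) - mean(g$b)) / sqrt(msw * (1 / 8 + 1 / 8))
  praw <- 2 * pt(abs(tstat), 32 - 4, lower.tail = FALSE)
  expect_equal(pw$p_raw[pw$pair == "a vs b"], praw, tolerance = 1e-12)
})

test_that("the classical unpaired t matches hand computation", {
  tt <- unpairedT(c(1, 2, 3), c(4, 5, 6))
  # explicit formula: diff / (sp * sqrt(1/n1 + 1/n2)), pooled sp = 1
  expect_equal(tt$t, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(round(tt$t, 3), -3.674)
  expect_equal(tt$df, 4)
  same <- rnorm(6)
  expect_equal(unpairedT(same, same)$t, 0)
  # Welch flag changes the degrees of freedom under unequal variances
  set.seed(53)
  a <- rnorm(10, sd = 1)
  b <- rnorm(10, sd = 5)
  expect_lt(unpairedT(a, b, welch = TRUE)$df, unpairedT(a, b)$df)
})

test_that("operator agreement combines the variance-ratio F with the t-test", {
  x <- c(10, 11, 12, 13, 14, 15, 16, 17, 18, 19)
  res <- fisherAgreement(x, x)
  expect_equal(res$F, 1)
  expect_true(res$agreement)
  idres <- fisherAgreement(rep(4, 5), rep(4, 5))
  expect_equal(idres$t, 0)
  expect_true(idres$agreement)
  # variance ratio 4 at n = 10 vs 10: p = 2 * (1 - pf(4, 9, 9))
  set.seed(54)
  a <- scale(rnorm(10))[, 1] * 2 # sd exactly 2
  b <- scale(rnorm(10))[, 1] * 1
  res2 <- fisherAgreement(a + 5, b + 5)
  expect_equal(res2$F, 4, tolerance = 1e-12)
  expect_equal(res2$pF, 2 * pf(4, 9, 9, lower.tail = FALSE), tolerance = 1e-12)
  # same-distribution operators agree at least 90% of the time
  set.seed(55)
  agree <- vapply(1:200, function(i) {
    fisherAgreement(rnorm(12, 100, 5), rnorm(12, 100, 5))$agreement
  }, logical(1))
  expect_gte(mean(agree), 0.9)
})

test_that("Pearson fits recover exact lines and match the covariance formula", {
  x <- 1:10
  res <- pearsonFit(x, 2 * x + 1)
  expect_equal(res$r, 1)
  expect_equal(res$slope, 2)
  expect_equal(res$intercept, 1)
  expect_equal(res$rSquared, 1)
  set.seed(56)
  for (i in 1:10) {
    xx <- rnorm(20)
    yy <- rnorm(20)
    res2 <- pearsonFit(xx, yy)
    rOracle <- sum((xx - mean(xx)) * (yy - mean(yy))) /
      sqrt(sum((xx - mean(xx))^2) * sum((yy - mean(yy))^2))
    expect_equal(res2$r, rOracle, tolerance = 1e-12)
    expect_equal(res2$rSquared, rOracle^2, tolerance = 1e-12)
    expect_lte(abs(res2$r), 1)
  }
  # shuffling y breaks the association
  yShuf <- sample(2 * x + 1)
  expect_lt(abs(pearsonFit(x, yShuf)$r), 0.9)
  expect_error(pearsonFit(1:5, rep(2, 5)), "variance")
})

test_that("correlation is affine-equivariant in sign and magnitude", {
  set.seed(57)
  x <- rnorm(15)
  y <- 0.7 * x + rnorm(15, sd = 0.4)
  r0 <- pearsonFit(x, y)$r
  expect_equal(pearsonFit(3 * x + 2, 0.5 * y - 7)$r, r0, tolerance = 1e-12)
  expect_equal(pearsonFit(-x, y)$r, -r0, tolerance = 1e-12)
})
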