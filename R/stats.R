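## The study's statistical battery: one-way ANOVA with Bonferroni pairwise
## correction, classical unpaired t, Fisher variance-ratio operator
## agreement, and Pearson correlation with an OLS fit. All tests delegate to
## the standard stats implementations behind a uniform interface.

.asGroups <- function(groups) {
  if (is.data.frame(groups)) {
    groups <- split(groups[[1L]], groups[[2L]])
  }
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    names(groups) <- paste0("g", seq_along(groups))
  }
  lapply(groups, as.numeric)
}

#' One-way ANOVA
#'
#' Classical between/within mean-square F with (k-1, N-k) degrees of
#' freedom. The degenerate case of zero between-group variance with zero
#' residual variance (all observations identical) is reported as
#' `F = 0, p = 1`.
#'
#' @param groups named list of numeric vectors (each n >= 2), or a
#'   two-column data.frame (value, group).
#' @param posthoc also run [bonferroniPairwise()] and attach the table.
#' @param alpha significance level for flags (default 0.05).
#' @return An object of class `groupComparison`: a list with `F`, `df`,
#'   `p`, group labels/sizes, and (optionally) the `pairwise` table.
#' @examples
#' oneWayAnova(list(a = rnorm(8), b = rnorm(8, 1), c = rnorm(8)))
#' @export
oneWayAnova <- function(groups, posthoc = FALSE, alpha = 0.05) {
  groups <- .asGroups(groups)
  stopifnot(all(lengths(groups) >= 2L))
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  k <- length(groups)
  N <- length(y)
  ssb <- sum(lengths(groups) * (vapply(groups, mean, 0) - mean(y))^2)
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 0))
  if (ssb < 1e-300) {
    f <- 0
    p <- 1
  } else if (ssw < 1e-300) { # groups differ with zero residual variance
    f <- Inf
    p <- 0
  } else {
    a <- stats::anova(stats::lm(y ~ g))
    f <- a[["F value"]][1L]
    p <- a[["Pr(>F)"]][1L]
  }
  res <- list(
    F = f, df = c(k - 1L, N - k), p = p,
    groups = names(groups), n = unname(lengths(groups)),
    means = unname(vapply(groups, mean, 0)),
    alpha = alpha, significant = is.finite(p) && p < alpha
  )
  if (posthoc) {
    res$pairwise <- bonferroniPairwise(groups, alpha = alpha)
  }
  class(res) <- "groupComparison"
  res
}

#' @export
print.groupComparison <- function(x, ...) {
  cat(sprintf(
    "One-way ANOVA: F(%d, %d) = %.4g, p = %.4g%s\n",
    x$df[1L], x$df[2L], x$F, x$p,
    if (x$significant) sprintf(" (significant at alpha = %g)", x$alpha) else ""
  ))
  cat(
    "  groups:",
    paste(sprintf("%s (n=%d, mean %.4g)", x$groups, x$n, x$means), collapse = ", "),
    "\n"
  )
  if (!is.null(x$pairwise)) {
    cat("  Bonferroni pairwise:\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}

#' Bonferroni-corrected pairwise comparisons
#'
#' All k(k-1)/2 pairwise two-sided t-tests with the adjusted p-value
#' `min(1, p * m)`, `m` the number of comparisons. By default the tests use
#' the pooled within-group standard deviation from the full design
#' (classical Bonferroni-protected comparisons, via
#' [stats::pairwise.t.test()] with `pool.sd = TRUE`); `pooled = FALSE`
#' switches to per-pair pooled variances.
#'
#' @param groups as in [oneWayAnova()].
#' @param pooled use the common within-group SD across all groups.
#' @param alpha significance level for the flag column.
#' @return data.frame with columns `pair`, `p_raw`, `p_adj`, `significant`.
#' @export
bonferroniPairwise <- function(groups, pooled = TRUE, alpha = 0.05) {
  groups <- .asGroups(groups)
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  raw <- stats::pairwise.t.test(y, g,
    p.adjust.method = "none",
    pool.sd = pooled, alternative = "two.sided"
  )$p.value
  pairs <- which(!is.na(raw), arr.ind = TRUE)
  m <- nrow(pairs)
  out <- data.frame(
    pair = sprintf("%s vs %s", colnames(raw)[pairs[, 2L]], rownames(raw)[pairs[, 1L]]),
    p_raw = raw[pairs],
    stringsAsFactors = FALSE
  )
  out$p_adj <- pmin(1, out$p_raw * m)
  out$significant <- out$p_adj < alpha
  out[order(out$pair), , drop = FALSE]
}

#' Unpaired two-sided Student's t-test
#'
#' Pooled-variance (classical) by default; `welch = TRUE` drops the equal
#' variance assumption.
#'
#' @param a,b numeric samples (n >= 2 each).
#' @param welch use the Welch correction.
#' @return list with `t`, `df`, `p`.
#' @export
unpairedT <- function(a, b, welch = FALSE) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  tt <- stats::t.test(a, b, var.equal = !welch)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Inter-operator agreement: Fisher F then unpaired t
#'
#' Checks that two operators' measurement sets are statistically
#' indistinguishable: first a two-sided variance-ratio F-test
#' (`F = larger variance / smaller variance`), then an unpaired t-test on
#' the means. Agreement requires both p-values above `alpha`. Two identical
#' constant-difference-free vectors (zero variance in both, equal means)
#' are reported as `F = 1, t = 0`, in agreement.
#'
#' @param operatorA,operatorB measurement vectors of the same items.
#' @param alpha significance level (default 0.05).
#' @return list with `F`, `dfF`, `pF`, `t`, `pT`, `agreement`.
#' @export
fisherAgreement <- function(operatorA, operatorB, alpha = 0.05) {
  stopifnot(length(operatorA) >= 2L, length(operatorB) >= 2L)
  va <- stats::var(operatorA)
  vb <- stats::var(operatorB)
  if (va == 0 && vb == 0) {
    eq <- isTRUE(all.equal(mean(operatorA), mean(operatorB)))
    return(list(
      F = 1, dfF = c(length(operatorA) - 1L, length(operatorB) - 1L), pF = 1,
      t = if (eq) 0 else Inf, pT = if (eq) 1 else 0,
      agreement = eq
    ))
  }
  if (va >= vb) {
    f <- va / vb
    dfs <- c(length(operatorA) - 1L, length(operatorB) - 1L)
  } else {
    f <- vb / va
    dfs <- c(length(operatorB) - 1L, length(operatorA) - 1L)
  }
  pF <- min(1, 2 * stats::pf(f, dfs[1L], dfs[2L], lower.tail = FALSE))
  tt <- unpairedT(operatorA, operatorB)
  list(
    F = f, dfF = dfs, pF = pF, t = tt$t, pT = tt$p,
    agreement = pF > alpha && tt$p > alpha
  )
}

#' Pearson correlation with ordinary least-squares fit
#'
#' @param x,y numeric vectors (n >= 3, nonzero variance each).
#' @return An object of class `correlationResult`: list with `r`,
#'   `rSquared` (= r^2), `slope`, `intercept`, `n`.
#' @examples
#' pearsonFit(1:10, 2 * (1:10) + 1)
#' @export
pearsonFit <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("x and y must both have nonzero variance")
  }
  r <- stats::cor(x, y)
  fit <- stats::lm(y ~ x)
  structure(
    list(
      r = r, rSquared = r^2,
      slope = unname(stats::coef(fit)[2L]),
      intercept = unname(stats::coef(fit)[1L]),
      n = length(x)
    ),
    class = "correlationResult"
  )
}

#' @export
print.correlationResult <- function(x, ...) {
  cat(sprintf(
    "Pearson fit (n = %d): r = %.4f, R^2 = %.4f, y = %.4g x + %.4g\n",
    x$n, x$r, x$rSquared, x$slope, x$intercept
  ))
  invisible(x)
}
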