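test_that("expected-count chooser picks Fisher for sparse tables and Yates otherwise", {
  sparse <- assocTest(3, 198, 7, 289)   # min expected ~ 4.04
  expect_identical(sparse$test_used, "fisher_exact")
  expect_equal(signif(sparse$p, 3), 0.747)
  dense <- assocTest(19, 182, 25, 271)
  expect_identical(dense$test_used, "chi2_yates")
  expect_equal(signif(dense$p, 3), 0.820)
})

test_that("Yates statistic clamps to zero for equal proportions", {
  res <- assocTest(5, 5, 5, 5)
  expect_identical(res$test_used, "chi2_yates")
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
})

test_that("degenerate tables are rejected", {
  expect_error(assocTest(0, 0, 3, 5), "degenerate table")
  expect_error(assocTest(0, 4, 0, 5), "degenerate table")
  expect_error(assocTest(2, -1, 3, 5), "non-negative")
})

test_that("association p is invariant to row and to column swaps", {
  set.seed(11)
  for (i in 1:25) {
    tab <- sample(0:12, 4, replace = TRUE)
    a <- tab[1]; b <- tab[2]; c <- tab[3]; d <- tab[4]
    if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) next
    p0 <- assocTest(a, b, c, d)$p
    expect_equal(assocTest(c, d, a, b)$p, p0)
    expect_equal(assocTest(b, a, d, c)$p, p0)
  }
})

test_that("both chooser branches agree with the standard-library tests", {
  set.seed(21)
  for (i in 1:30) {
    tab <- sample(0:25, 4, replace = TRUE) + c(1, 1, 1, 1)
    a <- tab[1]; b <- tab[2]; c <- tab[3]; d <- tab[4]
    m <- matrix(c(a, b, c, d), 2, byrow = TRUE)
    expect_equal(assocTest(a, b, c, d, force = "fisher_exact")$p,
                 stats::fisher.test(m)$p.value, tolerance = 1e-10)
    expect_equal(assocTest(a, b, c, d, force = "chi2_yates")$p,
                 suppressWarnings(stats::chisq.test(m, correct = TRUE))$p.value,
                 tolerance = 1e-10)
  }
})

test_that("Welch t matches the textbook formula and handles edge cases", {
  x <- c(2.1, 3.4, 1.9, 4.2, 2.8)
  y <- c(5.0, 6.1, 4.8, 5.5)
  res <- welchT(x, y)
  # hand oracle: direct Welch-Satterthwaite computation
  se2 <- var(x) / 5 + var(y) / 4
  tval <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((var(x) / 5)^2 / 4 + (var(y) / 4)^2 / 3)
  expect_equal(res$statistic, tval)
  expect_equal(res$p, 2 * pt(-abs(tval), df))
  expect_lt(welchT(x, y, tail = "greater")$p +
              welchT(y, x, tail = "greater")$p, 1.001)
  expect_equal(welchT(x, x)$p, 1)
  expect_equal(welchT(c(0, 0, 0, 0), c(1, 1, 1, 1) + 1e-9)$p, 0,
               tolerance = 1e-6)
  expect_equal(welchT(c(2, 2, 2), c(2, 2, 2))$p, 1)
  expect_error(welchT(c(1, NA, 2), y), "non-finite")
  expect_error(welchT(1, y), "at least 2")
})

test_that("Pearson correlation matches the covariance formula", {
  set.seed(5)
  x <- rnorm(20); y <- 0.6 * x + rnorm(20)
  res <- pearsonR(x, y)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, r_hand)
  expect_equal(pearsonR(x, x)$r, 1)
  expect_equal(pearsonR(x, -x)$r, -1)
  expect_error(pearsonR(x, rep(1, 20)), "constant")
  expect_error(pearsonR(x[1:2], y[1:2]), "at least 3")
})

test_that("log-rank agrees with a hand-computed O-E table and is label-symmetric", {
  # 6 subjects, distinct event times, no censoring
  t1 <- c(1, 3, 5); t2 <- c(2, 4, 6)
  res <- logrankTest(t1, c(TRUE, TRUE, TRUE), t2, c(TRUE, TRUE, TRUE))
  # manual log-rank over ordered event times
  times <- c(1, 2, 3, 4, 5, 6); grp <- c(1, 2, 1, 2, 1, 2)
  O <- E <- V <- 0
  for (k in seq_along(times)) {
    at1 <- sum(t1 >= times[k]); at2 <- sum(t2 >= times[k]); n <- at1 + at2
    d <- 1
    O <- O + (grp[k] == 1)
    E <- E + d * at1 / n
    if (n > 1) V <- V + d * (at1 / n) * (at2 / n) * (n - d) / (n - 1)
  }
  expect_equal(res$statistic, (O - E)^2 / V, tolerance = 1e-8)
  swapped <- logrankTest(t2, c(TRUE, TRUE, TRUE), t1, c(TRUE, TRUE, TRUE))
  expect_equal(res$p, swapped$p)
  same <- logrankTest(t1, c(TRUE, FALSE, TRUE), t1, c(TRUE, FALSE, TRUE))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p, 1)
  expect_error(logrankTest(t1, rep(FALSE, 3), t2, rep(FALSE, 3)),
               "no events")
  expect_error(logrankTest(c(-1, 2), c(TRUE, TRUE), t2, rep(TRUE, 3)),
               "positive")
})

test_that("log-rank p decreases along a simulated hazard-ratio sweep", {
  set.seed(31)
  pvals <- vapply(c(1, 2, 4), function(hr) {
    mean(replicate(20, {
      x <- rexp(60, 0.02); y <- rexp(60, 0.02 * hr)
      logrankTest(x, x < 50, y, y < 50)$p
    }))
  }, numeric(1))
  expect_true(all(diff(pvals) < 0))
})

test_that("group proportions divide by the full stratum size", {
  cl <- clinical(table1Cohort())
  expect_equal(round(groupProportion(cl, cl$group == "ERG_POS",
                                     cl$ancestry == "CA")), 47)
  expect_equal(round(groupProportion(cl, cl$group == "ERG_POS",
                                     cl$ancestry == "AA")), 35)
  expect_equal(groupProportion(cl, rep(FALSE, nrow(cl)),
                               cl$ancestry == "CA"), 0)
  expect_error(groupProportion(cl, cl$group == "ERG_POS",
                               rep(FALSE, nrow(cl))), "empty stratum")
})
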