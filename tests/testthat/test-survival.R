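test_that("product-limit estimate matches hand computation", {
  c1 <- kmEstimate(5, 1)
  expect_equal(c1@time, 5)
  expect_equal(c1@surv, 0)

  c2 <- kmEstimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(c2@surv, c(2 / 3, 1 / 3, 0))

  # censoring at 2 leaves the risk set after 2
  c3 <- kmEstimate(c(1, 2, 2, 3), c(1, 0, 1, 1))
  expect_equal(c3@time, c(1, 2, 3))
  expect_equal(c3@surv, c(3 / 4, 1 / 2, 0))

  expect_error(kmEstimate(numeric(), numeric()), "empty")
  expect_error(kmEstimate(c(-1, 2), c(1, 1)), "positive")
})

test_that("rmst integrates the survival step function", {
  allCens <- kmEstimate(rep(10, 5), rep(0, 5))
  expect_equal(rmst(allCens, tau = 10), 10)
  expect_equal(rmst(kmEstimate(5, 1), tau = 10), 5)
  expect_error(rmst(kmEstimate(5, 1), tau = 0), "positive")

  withr::with_seed(11, {
    tms <- rexp(400, 0.2)
    curve <- kmEstimate(tms, rep(1, 400))
    # uncensored, tau beyond the last time: area = arithmetic mean
    expect_equal(rmst(curve, tau = max(tms) + 1), mean(tms),
                 tolerance = 1e-10)
    # monotone non-decreasing in tau, bounded by tau
    taus <- c(1, 2, 5, 10, 20)
    vals <- vapply(taus, function(tt) rmst(curve, tt), numeric(1))
    expect_true(all(diff(vals) >= 0))
    expect_true(all(vals <= taus))
  })
})

test_that("log-rank agrees with the observed-minus-expected oracle", {
  t1 <- c(3, 5, 7, 9, 11, 14); e1 <- c(1, 1, 0, 1, 1, 0)
  t2 <- c(2, 4, 6, 8, 10, 12); e2 <- c(1, 1, 1, 0, 1, 1)
  got <- logrankTest(t1, e1, t2, e2)
  want <- logrankOracle(t1, e1, t2, e2)
  expect_equal(got$chi_square, want$chi_square, tolerance = 1e-8)
  expect_equal(got$p_value, want$p_value, tolerance = 1e-8)
  # symmetric in group order
  swapped <- logrankTest(t2, e2, t1, e1)
  expect_equal(got$chi_square, swapped$chi_square, tolerance = 1e-12)
})

test_that("log-rank degenerate cases", {
  ident <- logrankTest(c(1, 2, 3), c(1, 0, 1), c(1, 2, 3), c(1, 0, 1))
  expect_equal(ident$chi_square, 0, tolerance = 1e-12)
  expect_equal(ident$p_value, 1, tolerance = 1e-12)
  noEvents <- logrankTest(c(1, 2), c(0, 0), c(3, 4), c(0, 0))
  expect_identical(noEvents$chi_square, 0)
  expect_identical(noEvents$p_value, 1)
  expect_error(logrankTest(numeric(), numeric(), 1, 1), "non-empty")
})

test_that("Cox fit maximizes the Breslow partial likelihood", {
  withr::with_seed(23, {
    for (rep in 1:5) {
      n <- 10
      x <- rnorm(n)
      tms <- rexp(n, exp(0.5 * x))
      ev <- rbinom(n, 1, 0.8)
      if (sum(ev) < 2) next
      fit <- coxUnivariate(tms, ev, x)
      expect_equal(fit$beta, coxGridOracle(tms, ev, x), tolerance = 1e-3)
    }
  })
})

test_that("Cox beta is antisymmetric under covariate negation", {
  withr::with_seed(31, {
    x <- rnorm(50)
    tms <- rexp(50, exp(0.7 * x))
    ev <- rbinom(50, 1, 0.9)
    f1 <- coxUnivariate(tms, ev, x)
    f2 <- coxUnivariate(tms, ev, -x)
    expect_equal(f1$beta, -f2$beta, tolerance = 1e-9)
    expect_equal(f1$p_value, f2$p_value, tolerance = 1e-12)
  })
  expect_error(coxUnivariate(c(1, 2, 3), c(1, 1, 1), rep(2, 3)), "constant")
  expect_error(coxUnivariate(c(1, 2, 3), c(1, 0, 0), c(1, 2, 3)),
               "2 events")
})

test_that("Cox null calibration with a binary covariate", {
  ok <- vapply(1:20, function(s) withr::with_seed(1000 + s, {
    x <- rep(0:1, each = 1000)
    tms <- rexp(2000, 0.1)          # same law in both groups
    fit <- coxUnivariate(tms, rep(1, 2000), x)
    abs(fit$beta) < 0.1 && fit$p_value > 0.05
  }), logical(1))
  expect_gte(mean(ok), 0.90)
})

test_that("perfect separation is flagged, not silently reported", {
  # survival time exactly ordered by x: monotone likelihood
  x <- 1:20
  tms <- seq(1, 20)
  fit <- coxUnivariate(tms, rep(1, 20), x)
  expect_false(fit$converged)
})

test_that("cutoff scan finds forced separation with direction +1", {
  withr::with_seed(17, {
    tms <- rexp(200, 0.1)
    sc <- kmCutoffScan(tms, tms, rep(1, 200))  # x = survival time itself
    expect_identical(sc$direction, 1L)
    expect_lt(sc$min_logrank_p, 1e-4)
    qs <- quantile(tms, c(0.05, 0.95))
    expect_gte(sc$best_cutoff, qs[[1]])
    expect_lte(sc$best_cutoff, qs[[2]])
  })
})

test_that("cutoff scan is a pure function of the data", {
  withr::with_seed(19, {
    x <- sample(rep(1:6, times = c(10, 8, 12, 9, 6, 5)))
    tms <- rexp(50, 0.1 * x)
    ev <- rbinom(50, 1, 0.8)
    s1 <- kmCutoffScan(x, tms, ev, useAllValues = TRUE)
    s2 <- kmCutoffScan(x, tms, ev, useAllValues = TRUE)
    expect_identical(s1, s2)
    # duplicated covariate values collapse to one candidate cutoff each
    expect_lte(s1$n_cutoffs_tested, length(unique(x)))
  })
  expect_error(kmCutoffScan(rep(1, 10), rexp(10), rep(1, 10)), "constant")
})

test_that("null cutoff scan is anti-conservative (it really scans)", {
  sig <- vapply(1:100, function(s) withr::with_seed(2000 + s, {
    x <- rnorm(100)
    tms <- rexp(100, 0.1)
    kmCutoffScan(x, tms, rep(1, 100))$min_logrank_p < 0.05
  }), logical(1))
  expect_gt(mean(sig), 0.05)  # inflated type I: the minimum over a grid
})
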