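test_that("the power-law fit is exact on noiseless log-linear data", {
  f <- powerlawFit(c(1, 4, 9), 2 * c(1, 4, 9)^0.5)
  expect_equal(f@alpha, 0.5, tolerance = 1e-12)
  expect_equal(f@beta, 2, tolerance = 1e-12)
  expect_equal(f@rLog, 1, tolerance = 1e-12)
})

test_that("the OLS solution equals the closed-form normal equations", {
  set.seed(2)
  for (i in 1:10) {
    a <- exp(rnorm(3, 1)); r <- exp(rnorm(3, 2))
    f <- powerlawFit(a, r)
    x <- log(a); y <- log(r)
    slope <- (sum(x * y) - length(x) * mean(x) * mean(y)) /
      (sum(x^2) - length(x) * mean(x)^2)
    intercept <- mean(y) - slope * mean(x)
    expect_equal(f@alpha, slope, tolerance = 1e-12)
    expect_equal(f@beta, exp(intercept), tolerance = 1e-12)
  }
  expect_error(powerlawFit(c(-1, 2, 3), c(1, 2, 3)), "positive")
})

test_that("the power-law fit is scale equivariant", {
  set.seed(3)
  a <- exp(rnorm(15, 1.5, 0.8))
  r <- 6.8 * a^0.35 * exp(rnorm(15, 0, 0.3))
  f1 <- powerlawFit(a, r)
  f2 <- powerlawFit(a * 4, r)
  expect_equal(f2@alpha, f1@alpha, tolerance = 1e-9)
  expect_equal(f2@beta, f1@beta * 4^(-f1@alpha), tolerance = 1e-9)
})

test_that("correlations reproduce the prespike worked example", {
  amp <- c(0.11, 0.26, 0.30, 0.37)
  area <- c(19.2, 23.1, 25.6, 59.7)
  expect_equal(round(pearsonR(amp, area), 1), 0.8)
  expect_equal(spearmanRho(amp, area), 1.0)
  expect_equal(pearsonR(1:10, 2 * (1:10) + 3), 1)
  expect_error(pearsonR(rep(1, 5), 1:5), "zero-variance")
  ## rho is invariant under monotone transforms
  set.seed(4)
  x <- rnorm(20); y <- rnorm(20)
  expect_equal(spearmanRho(x, y), spearmanRho(exp(x), y), tolerance = 1e-12)
  expect_equal(spearmanRho(x, y), spearmanRho(x, y^3 + y), tolerance = 1e-12)
})

test_that("simple regression matches the reference implementation", {
  set.seed(5)
  for (i in 1:10) {
    x <- rnorm(12); y <- 2 * x + rnorm(12)
    r <- regressionF(x, y)
    s <- summary(lm(y ~ x))
    expect_equal(r$coefficients$estimate, unname(s$coefficients[, 1]),
                 tolerance = 1e-10)
    expect_equal(r$F, unname(s$fstatistic[1]), tolerance = 1e-10)
  }
  ## age-corrected (two-predictor) variant
  x <- rnorm(15); age <- runif(15, 2, 8); y <- x + 0.5 * age + rnorm(15)
  r2 <- regressionF(x, y, covariate = age)
  s2 <- summary(lm(y ~ x + age))
  expect_equal(r2$coefficients$estimate, unname(s2$coefficients[, 1]),
               tolerance = 1e-10)
  expect_equal(r2$df1, 2L); expect_equal(r2$df2, 12L)
  ## rank transform equals lm on midranks
  r3 <- regressionF(x, y, rankTransform = TRUE)
  s3 <- summary(lm(rank(y) ~ rank(x)))
  expect_equal(r3$F, unname(s3$fstatistic[1]), tolerance = 1e-10)
  ## perfect fit reports infinite F; collinearity errors
  r4 <- regressionF(1:8, 3 * (1:8) + 2)
  expect_true(is.infinite(r4$F))
  expect_equal(r4$p, 0)
  expect_error(regressionF(1:8, rnorm(8), covariate = 2 * (1:8)),
               "rank-deficient")
})

test_that("the amplitude-area worked example gives F(1,2) about 3", {
  r <- regressionF(c(19.2, 23.1, 25.6, 59.7), c(0.11, 0.26, 0.30, 0.37))
  expect_equal(r$df1, 1L)
  expect_equal(r$df2, 2L)
  expect_equal(round(r$F), 3)
})

test_that("Bonferroni correction multiplies and clips", {
  expect_equal(bonferroni(0.0005, 2), 0.001)
  expect_equal(bonferroni(0.8, 2), 1.0)
  expect_equal(bonferroni(0.03, 1), 0.03)
  expect_equal(bonferroni(c(0.01, 0.04), 4), c(0.04, 0.16))
  expect_error(bonferroni(c(0.1, 0.2), 1), "at least")
})

test_that("the logistic fit honours symmetry and flags separation", {
  ages <- rep(c(3, 5), each = 20)
  pres <- rep(c(FALSE, TRUE), each = 20)
  ## jitter one observation per class to avoid perfect separation
  ages <- c(ages, 4, 4); pres <- c(pres, TRUE, FALSE)
  f <- logisticFit(ages, pres)
  expect_equal(f@midpoint, 4.0, tolerance = 0.05)
  ## fully separated data is flagged
  sep <- logisticFit(rep(c(3, 5), each = 10), rep(c(FALSE, TRUE), each = 10))
  expect_false(sep@converged)
  expect_error(logisticFit(1:5, rep(TRUE, 5)), "both outcome classes")
})

test_that("the logistic fit recovers the prespike-onset parameters", {
  ms <- ss <- numeric(40)
  set.seed(8)
  for (i in 1:40) {
    age <- runif(200, 2, 8)
    pres <- runif(200) < stats::plogis((age - 4.1) / 0.7)
    f <- logisticFit(age, pres)
    ms[i] <- f@midpoint; ss[i] <- f@steepness
  }
  expect_lte(abs(median(ms) - 4.1), 0.2)
  expect_lte(abs(median(ss) - 0.7), 0.2)
})

test_that("conduction speed follows the latency arithmetic", {
  expect_equal(conductionSpeed(2.1), 0.625, tolerance = 1e-12)
  expect_equal(round(conductionSpeed(2.1), 1), 0.6)
  expect_equal(conductionSpeed(1.5), 1.0)
  expect_equal(conductionSpeed(2.5), 0.5)
  expect_error(conductionSpeed(0.4), "exceed")
})

test_that("Welch's t test matches hand computation and t.test", {
  w <- welchTTest(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$t, -3.674, tolerance = 1e-3)
  expect_equal(w$df, 4, tolerance = 1e-9)
  x <- c(2, 2, 2); y <- c(2, 2, 2)
  w0 <- welchTTest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(w0$t, 0)
  expect_equal(w0$p, 1)
  set.seed(9)
  for (i in 1:10) {
    a <- rnorm(14); b <- rnorm(9, 0.4)
    w1 <- welchTTest(a, b)
    ref <- t.test(a, b)
    expect_equal(w1$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(w1$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(w1$p, ref$p.value, tolerance = 1e-10)
  }
})
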