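#' @include AllClasses.R utils.R
NULL

#' Fit the structure-function power law
#'
#' Ordinary least squares of `log(ror)` on `log(area)` gives
#' `ror = beta * area^alpha` with `alpha` the slope and `beta` the
#' exponentiated intercept (standard error by the delta method). `rLog` is
#' the Pearson correlation of the log pairs. A nonlinear least-squares
#' refinement on the raw scale is available via `method = "nls"`.
#'
#' @param areas contact areas, µm² (positive).
#' @param rors EPSP rates of rise, V/s (positive).
#' @param method "ols" (log-log least squares, default) or "nls".
#' @return a [PowerLawFit-class].
#' @export
#' @examples
#' f <- powerlawFit(c(1, 4, 9), 2 * c(1, 4, 9)^0.5)
#' f  # alpha 0.5, beta 2
powerlawFit <- function(areas, rors, method = c("ols", "nls")) {
  method <- match.arg(method)
  stopifnot1(length(areas) == length(rors), "areas and rors must match")
  stopifnot1(length(areas) >= 3, "need at least 3 cells")
  stopifnot1(all(areas > 0) && all(rors > 0),
             "areas and rors must be positive")
  lx <- log(areas); ly <- log(rors)
  fit <- lm(ly ~ lx)
  sm <- summary(fit)
  alpha <- unname(coef(fit)[2])
  beta <- exp(unname(coef(fit)[1]))
  seA <- sm$coefficients[2, 2]
  seB <- beta * sm$coefficients[1, 2]
  if (method == "nls") {
    nl <- try(stats::nls(rors ~ b * areas^a,
                         start = list(b = beta, a = alpha)), silent = TRUE)
    if (!inherits(nl, "try-error")) {
      cf <- summary(nl)$coefficients
      beta <- cf["b", 1]; alpha <- cf["a", 1]
      seB <- cf["b", 2]; seA <- cf["a", 2]
    }
  }
  Fv <- if (sm$sigma == 0) Inf else unname(sm$fstatistic[1])
  pv <- if (is.infinite(Fv)) 0 else
    pf(Fv, sm$fstatistic[2], sm$fstatistic[3], lower.tail = FALSE)
  new("PowerLawFit", beta = beta, alpha = alpha, seBeta = seB, seAlpha = seA,
      rLog = cor(lx, ly), Fstat = Fv, p = pv, n = length(areas))
}

#' Pearson and Spearman correlation
#'
#' `pearsonR` is the product-moment correlation; `spearmanRho` is the Pearson
#' correlation of midranks. Zero-variance input is signalled as an error.
#'
#' @param x,y numeric vectors, n >= 3.
#' @return the correlation coefficient.
#' @export
#' @examples
#' pearsonR(c(0.11, 0.26, 0.30, 0.37), c(19.2, 23.1, 25.6, 59.7))  # ~0.8
pearsonR <- function(x, y) {
  stopifnot1(length(x) == length(y) && length(x) >= 3, "need n >= 3 pairs")
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined for zero-variance input", call. = FALSE)
  cor(x, y)
}

#' @rdname pearsonR
#' @export
spearmanRho <- function(x, y) {
  pearsonR(rank(x), rank(y))
}

#' Simple/one-covariate linear regression with F statistic
#'
#' OLS of `y` on `x`, optionally age-corrected by adding `covariate` as an
#' explanatory variable, and optionally computed on midranks (for outcomes
#' with non-normal residuals). Reports per-coefficient t and two-sided p,
#' and the overall F with its degrees of freedom. A perfectly linear fit
#' reports `F = Inf` with zero residual sum of squares.
#'
#' @param x predictor.
#' @param y outcome.
#' @param covariate optional second predictor (e.g. age).
#' @param rankTransform replace outcome and predictors by midranks.
#' @return list of class `"RegressionResult"`: `coefficients` (data.frame
#'   with estimate, se, t, p), `F`, `df1`, `df2`, `p`, `n`, `sigma`.
#' @export
regressionF <- function(x, y, covariate = NULL, rankTransform = FALSE) {
  n <- length(y)
  k <- 1L + !is.null(covariate)
  stopifnot1(n > k + 1L, "too few observations for the requested model")
  if (rankTransform) {
    x <- rank(x); y <- rank(y)
    if (!is.null(covariate)) covariate <- rank(covariate)
  }
  X <- if (is.null(covariate)) cbind(1, x) else cbind(1, x, covariate)
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient (collinear) design", call. = FALSE)
  df <- if (is.null(covariate)) data.frame(y = y, x = x) else
    data.frame(y = y, x = x, covariate = covariate)
  fit <- lm(y ~ ., data = df)
  sm <- summary(fit)
  cf <- as.data.frame(sm$coefficients)
  names(cf) <- c("estimate", "se", "t", "p")
  ssr <- sum(fit$residuals^2)
  ssy <- sum((y - mean(y))^2)
  Fv <- if (ssr <= 1e-12 * max(ssy, 1)) Inf else unname(sm$fstatistic[1])
  pv <- if (is.infinite(Fv)) 0 else
    pf(Fv, k, n - k - 1L, lower.tail = FALSE)
  structure(list(coefficients = cf, F = Fv, df1 = k, df2 = n - k - 1L,
                 p = pv, n = n, sigma = sm$sigma),
            class = "RegressionResult")
}

#' @export
print.RegressionResult <- function(x, ...) {
  cat(sprintf("Linear regression: F(%d,%d) = %.3g, p = %.3g, n = %d\n",
              x$df1, x$df2, x$F, x$p, x$n))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Bonferroni correction
#'
#' `p_corr = min(1, m * p)` for follow-up testing on the same data.
#'
#' @param p p values.
#' @param m number of tests in the family (at least `length(p)`).
#' @return corrected p values.
#' @export
#' @examples
#' bonferroni(0.0005, 2)  # 0.001
bonferroni <- function(p, m = length(p)) {
  stopifnot1(m >= length(p), "m must be at least the number of tests")
  stats::p.adjust(p, method = "bonferroni", n = m)
}

#' Logistic fit of a developmental onset
#'
#' Maximum-likelihood fit of `P(present | age) = 1/(1 + exp(-(age - m)/s))`
#' via iteratively reweighted least squares. Under (quasi-)separation the
#' steepness is bounded below at 0.1 days and the fit flagged non-converged.
#'
#' @param ages ages, days.
#' @param present logical (or 0/1) outcome.
#' @return a [LogisticFit-class].
#' @export
logisticFit <- function(ages, present) {
  present <- as.logical(present)
  stopifnot1(length(ages) == length(present), "ages and present must match")
  stopifnot1(any(present) && any(!present),
             "logistic fit needs both outcome classes")
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(present ~ ages, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities|did not converge", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  b <- coef(fit)
  V <- vcov(fit)
  if (b[2] <= 0) {
    ## decreasing or flat: report with sign, flag non-convergence of the
    ## onset parametrisation
    sep <- TRUE
  }
  s <- 1 / b[2]
  m <- -b[1] / b[2]
  J <- rbind(c(-1 / b[2], b[1] / b[2]^2),  # dm/db
             c(0, -1 / b[2]^2))            # ds/db
  Vp <- J %*% V %*% t(J)
  seM <- sqrt(max(0, Vp[1, 1]))
  seS <- sqrt(max(0, Vp[2, 2]))
  conv <- fit$converged && !sep && abs(s) >= 0.1
  if (sep || abs(s) < 0.1) {
    s <- sign(s) * max(abs(s), 0.1)
    conv <- FALSE
  }
  new("LogisticFit", midpoint = unname(m), steepness = unname(s),
      seM = unname(seM), seS = unname(seS), converged = conv)
}

#' Axonal conduction speed from EPSP latency
#'
#' `speed = axonLength / (latency - synapticDelay)`, neglecting the AP
#' initiation time.
#'
#' @param latency EPSP latency, ms.
#' @param axonLength assumed axon length, mm.
#' @param synapticDelay assumed synaptic delay, ms.
#' @return conduction speed, m/s.
#' @export
#' @examples
#' conductionSpeed(2.1)  # 0.625 -> rounds to 0.6 m/s
conductionSpeed <- function(latency, axonLength = 1, synapticDelay = 0.5) {
  stopifnot1(all(latency > synapticDelay),
             "latency must exceed the synaptic delay")
  axonLength / (latency - synapticDelay)
}

#' Welch's two-sample t test
#'
#' Signed Welch statistic with Satterthwaite degrees of freedom and a
#' two-sided p value.
#'
#' @param x,y numeric samples, each n >= 2.
#' @return list with `t`, `df`, `p`, `meanDiff`.
#' @export
#' @examples
#' welchTTest(c(1, 2, 3), c(4, 5, 6))
welchTTest <- function(x, y) {
  stopifnot1(length(x) >= 2 && length(y) >= 2,
             "each group needs at least 2 values")
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df), meanDiff = mean(x) - mean(y))
}
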