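test_that("single perfect predictor gives gof = [0, 1]", {
  d <- hp_data(as.numeric(1:10), matrix(as.numeric(1:10), 10, 1), names = "x")
  tab <- fit_all_subsets(d)
  expect_equal(tab$gof, c(0, 1))
})

test_that("orthonormal predictors: R-squared matches the lm oracle and adds", {
  set.seed(11)
  n <- 20
  A <- scale(matrix(rnorm(2 * n), n, 2), center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(A))                       # orthonormal, centred columns
  y <- 0.8 * Q[, 1] + 0.4 * Q[, 2] + rnorm(n, sd = 0.3)
  d <- hp_data(y, Q, names = c("x1", "x2"))
  tab <- fit_all_subsets(d)
  r2 <- function(fml) summary(lm(fml))$r.squared
  expect_equal(tab$gof[2], r2(y ~ Q[, 1]), tolerance = 1e-12)
  expect_equal(tab$gof[3], r2(y ~ Q[, 2]), tolerance = 1e-12)
  expect_equal(tab$gof[4], r2(y ~ Q), tolerance = 1e-12)
  expect_equal(tab$gof[4], tab$gof[2] + tab$gof[3], tolerance = 1e-10)
})

test_that("binomial null log-likelihood matches the closed form", {
  y <- c(rep(1, 62), rep(0, 58))
  set.seed(4)
  d <- hp_data(y, matrix(rnorm(240), 120, 2), names = c("a", "b"),
               family = "binomial")
  tab <- fit_all_subsets(d, gof_spec("loglik", "binomial"))
  expect_equal(tab$gof[1], 62 * log(62 / 120) + 58 * log(58 / 120),
               tolerance = 1e-10)
})

test_that("goodness-of-fit is monotone under subset inclusion", {
  set.seed(21)
  n <- 40; k <- 5
  X <- matrix(rnorm(n * k), n, k)
  d <- hp_data(rnorm(n) + X[, 1], X, names = letters[1:k])
  for (spec in list(gof_spec("rsqu", "gaussian"),
                    gof_spec("loglik", "gaussian"))) {
    gof <- fit_all_subsets(d, spec)$gof
    for (m in 0:(2^k - 1)) {
      for (i in 1:k) {
        bit <- bitwShiftL(1L, i - 1L)
        if (bitwAnd(m, bit) == 0L)
          expect_gte(gof[m + bit + 1L], gof[m + 1L] - 1e-8)
      }
    }
  }
})

test_that("nested binomial log-likelihoods are monotone", {
  set.seed(31)
  n <- 60; k <- 4
  X <- matrix(rnorm(n * k), n, k)
  y <- rbinom(n, 1, plogis(X[, 1] - 0.5 * X[, 2]))
  d <- hp_data(y, X, names = letters[1:k], family = "binomial")
  gof <- fit_all_subsets(d, gof_spec("loglik", "binomial"))$gof
  for (m in 0:(2^k - 1))
    for (i in 1:k) {
      bit <- bitwShiftL(1L, i - 1L)
      if (bitwAnd(m, bit) == 0L)
        expect_gte(gof[m + bit + 1L], gof[m + 1L] - 1e-8)
    }
})

test_that("the fit table is exactly invariant to predictor column order", {
  set.seed(41)
  X <- matrix(rnorm(25 * 5), 25, 5)
  y <- rnorm(25)
  d1 <- hp_data(y, X, names = letters[1:5])
  perm <- c(4, 2, 5, 1, 3)
  d2 <- hp_data(y, X[, perm], names = letters[1:5][perm])
  expect_identical(fit_all_subsets(d1)$gof, fit_all_subsets(d2)$gof)
  expect_identical(fit_all_subsets(d1)$names, fit_all_subsets(d2)$names)
})

test_that("predictor cap is enforced with an informative error", {
  set.seed(51)
  d <- hp_data(rnorm(40), matrix(rnorm(40 * 13), 40, 13))
  expect_error(fit_all_subsets(d), "cap of 12")
  expect_error(fit_all_subsets(d, cap = 17L), "16")
  expect_silent(tab <- fit_all_subsets(d, cap = 13L))
  expect_length(tab$gof, 2^13)
})

test_that("rank-deficient subsets are fitted with a warning, not an error", {
  set.seed(61)
  x <- rnorm(20)
  X <- cbind(x, x, rnorm(20))   # duplicated column
  d <- hp_data(rnorm(20), X, names = c("a", "b", "c"))
  expect_warning(tab <- fit_all_subsets(d), "rank-deficient")
  expect_true(all(is.finite(tab$gof)))
})

test_that("piecewise threshold is recovered for a logistic hinge", {
  set.seed(71)
  n <- 500
  x <- runif(n, -1, 2)
  p <- plogis(-2 + 5 * pmax(x - 0.5, 0))
  y <- rbinom(n, 1, p)
  res <- select_piecewise_threshold(x, y, family = "binomial")
  expect_false(res$no_threshold)
  expect_lt(abs(res$threshold - 0.5), 0.2)
  # brute-force oracle over the same grid
  ux <- sort(unique(x))
  q <- quantile(x, c(.1, .9), names = FALSE)
  cand <- ux[ux >= q[1] & ux <= q[2]]
  devs <- vapply(cand, function(t)
    deviance(glm(y ~ pmin(x, t) + pmax(x - t, 0), family = binomial)),
    numeric(1))
  expect_equal(res$threshold, cand[which.min(devs)])
  expect_equal(res$deviance, min(devs), tolerance = 1e-8)
})

test_that("an exactly linear relationship yields the no-threshold flag", {
  x <- seq(0, 1, length.out = 60)
  res <- select_piecewise_threshold(x, 3 * x - 1, family = "gaussian")
  expect_true(res$no_threshold)
  expect_true(is.na(res$threshold))
})

test_that("a gaussian hinge relationship recovers its knee tightly", {
  set.seed(91)
  x <- runif(300)
  y <- 2 * pmax(x - 0.5, 0) + rnorm(300, sd = 0.05)
  res <- select_piecewise_threshold(x, y, family = "gaussian")
  expect_false(res$no_threshold)
  expect_lt(abs(res$threshold - 0.5), 0.05)
})

test_that("a step response matches the brute-force deviance scan", {
  set.seed(81)
  x <- runif(200)
  y <- as.numeric(x > median(x)) + rnorm(200, sd = 0.05)
  res <- select_piecewise_threshold(x, y, family = "gaussian")
  expect_false(res$no_threshold)
  ux <- sort(unique(x))
  q <- quantile(x, c(.1, .9), names = FALSE)
  cand <- ux[ux >= q[1] & ux <= q[2]]
  devs <- vapply(cand, function(t)
    deviance(lm(y ~ pmin(x, t) + pmax(x - t, 0))), numeric(1))
  expect_equal(res$threshold, cand[which.min(devs)])
  expect_equal(res$deviance, min(devs), tolerance = 1e-10)
  # a continuous hinge basis puts its knee at or before a hard jump so the
  # rising segment can span the step; the jump must lie on that segment
  expect_lte(res$threshold, median(x))
  expect_lt(median(x) - res$threshold, 0.35)
})

test_that("too few distinct values is an error", {
  expect_error(
    select_piecewise_threshold(rep(1:5, 10), rnorm(50), family = "gaussian"),
    "10 distinct")
})

test_that("rsqu requires the gaussian family", {
  expect_error(gof_spec("rsqu", "binomial"), "gaussian")
})
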