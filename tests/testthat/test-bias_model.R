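test_that("spacing features match the printed-table subtractions", {
  cp <- setNames(rep(50, 5), names(kestrel_ive)[c(1, 7, 4, 8, 3)])
  ft <- compute_features(kestrel_ive[c(1, 7, 4, 8, 3)], change_pct = cp,
                         dataset = "kestrel")
  expect_equal(ft$variable,
               c("AUTOCOV4", "FARMLAND", "DROOST", "FOREST", "DCOLONY10"))
  expect_equal(ft$DIFPREVIOUS[ft$variable == "DCOLONY10"], 0.88,
               tolerance = 1e-12)
  expect_equal(ft$DIFPREVIOUS[ft$variable == "DROOST"], 1.16,
               tolerance = 1e-12)
  expect_true(is.na(ft$DIFPREVIOUS[1]))
  expect_true(is.na(ft$DIFNEXT[5]))
  expect_equal(ft$VARIABLES, rep(5L, 5))
})

test_that("equal IVEs give all-zero spacings", {
  v <- c(a = 2, b = 2, c = 2, d = 2)
  ft <- suppressWarnings(
    compute_features(v, change_pct = setNames(rep(0, 4), names(v))))
  dif <- as.matrix(ft[c("DIFNEXT", "DIFPREVIOUS", "DIFSECOND", "DIFTHIRD",
                        "DIFNEXTPREVIOUS", "DIFALL")])
  expect_true(all(dif[!is.na(dif)] == 0))
})

test_that("fewer than 4 variables is an error", {
  expect_error(compute_features(c(a = 1, b = 2, c = 3),
                                change_pct = c(a = 0, b = 0, c = 0)),
               "at least 4")
})

test_that("arcsine transform hits its closed-form anchors", {
  expect_equal(transform_response(0), 0)
  expect_equal(transform_response(100), pi / 2)
  expect_equal(transform_response(50), asin(0.5))
  expect_equal(transform_response(50, variance_stabilizing = TRUE),
               asin(sqrt(0.5)))
  expect_error(transform_response(120), "0, 100")
})

test_that("collinearity screen flags duplicated and monotone columns only", {
  set.seed(14)
  df <- data.frame(A = runif(1000))
  df$B <- df$A
  df$C <- exp(df$A)          # monotone transform: Spearman rho = 1
  df$D <- runif(1000)        # independent
  forb <- screen_collinearity(df, terms = c("A", "B", "C", "D"))
  pairs <- paste(forb$var1, forb$var2)
  expect_true(all(c("A B", "A C", "B C") %in% pairs))
  expect_false(any(grepl("D", pairs)))
})

test_that("model enumeration respects forbidden pairs", {
  expect_length(enumerate_models(c("A", "B")), 4)
  forb <- data.frame(var1 = "A", var2 = "B")
  expect_length(enumerate_models(c("A", "B"), forb), 3)
  trio <- enumerate_models(c("DIFPREVIOUS", "VARIABLES", "DIFALL"))
  expect_length(trio, 8)
  expect_identical(trio[[1]], character(0))
})

test_that("the mixed model recovers a known spacing slope", {
  ft <- simulate_feature_table(seed = 33)
  truth <- attr(ft, "truth")
  f <- fit_candidate("DIFPREVIOUS", ft)
  expect_equal(f$method, "lmm")
  slope <- f$coef[["DIFPREVIOUS"]]
  se <- f$se[[which(names(f$coef) == "DIFPREVIOUS")]]
  expect_lt(slope, 0)
  expect_lt(abs(slope - truth[["beta_dif"]]), 2 * se)
})

test_that("a single dataset falls back to least squares with a warning", {
  ft <- simulate_feature_table(k_values = 10L, seed = 2)
  expect_warning(f <- fit_candidate("DIFPREVIOUS", ft), "least squares")
  expect_equal(f$method, "ols")
})

test_that("the null model's intercept is the grand mean", {
  ft <- simulate_feature_table(seed = 3)
  f <- suppressWarnings(fit_candidate(character(0), ft))
  expect_equal(unname(f$coef[["(Intercept)"]]), mean(ft$change_asin),
               tolerance = 0.05)
})

test_that("AICc ranking arithmetic behaves at the edges", {
  one <- fake_fit("only", c(`(Intercept)` = 1), c(`(Intercept)` = .1),
                  AIC = 10, p = 2, n = 30)
  rk <- rank_models(list(one))
  expect_equal(rk$weight, 1)
  two <- list(
    fake_fit("a", c(`(Intercept)` = 1), c(`(Intercept)` = .1), 10, 2, 30),
    fake_fit("b", c(`(Intercept)` = 2), c(`(Intercept)` = .1), 10, 2, 30))
  rk2 <- rank_models(two)
  expect_equal(rk2$weight, c(0.5, 0.5))
  expect_true(all(rk2$in_confidence_set))
  expect_error(rank_models(list(fake_fit("x", c(`(Intercept)` = 1),
                                         c(`(Intercept)` = .1), 5, 5, 6))),
               "AICc undefined")
})

test_that("AICc converges to AIC for large n", {
  f <- fake_fit("big", c(`(Intercept)` = 0), c(`(Intercept)` = 1),
                AIC = 100, p = 4, n = 1e6)
  rk <- rank_models(list(f))
  expect_lt(rk$AICc - rk$AIC, 1e-4)
})

test_that("weights decrease with AICc and sum to one", {
  aw <- akaike_weights(c(101, 95, 130, 99))
  expect_equal(sum(aw$weight), 1)
  expect_true(all(diff(aw$weight[order(aw$aicc)]) <= 0))
})

test_that("model averaging does shrinkage arithmetic correctly", {
  a <- fake_fit("A", c(`(Intercept)` = 0.5, X = 2),
                c(`(Intercept)` = 0.1, X = 0.2), AIC = 10, p = 3, n = 50)
  b <- fake_fit("Null model", c(`(Intercept)` = 1),
                c(`(Intercept)` = 0.1), AIC = 10, p = 2, n = 50)
  rk <- rank_models(list(a, b))
  avg <- average_models(rk)
  cf <- setNames(avg$coefficients$estimate, avg$coefficients$term)
  # AICc differs slightly (p differs), so compute the exact expected weights
  w <- rk$weight / sum(rk$weight)
  wA <- w[rk$model == "A"]
  expect_equal(unname(cf["X"]), unname(2 * wA), tolerance = 1e-12)
  expect_equal(unname(cf["(Intercept)"]),
               unname(0.5 * wA + 1 * (1 - wA)), tolerance = 1e-12)
  # a one-model confidence set reduces to that model
  c1 <- fake_fit("best", c(`(Intercept)` = 0.3, X = -1),
                 c(`(Intercept)` = .1, X = .1), AIC = 10, p = 3, n = 50)
  c2 <- fake_fit("bad", c(`(Intercept)` = 0), c(`(Intercept)` = .1),
                 AIC = 40, p = 2, n = 50)
  avg1 <- average_models(rank_models(list(c1, c2)))
  expect_equal(setNames(avg1$coefficients$estimate, avg1$coefficients$term),
               c1$coef)
})

test_that("hand-computed weighted averages match average_models", {
  f1 <- fake_fit("m1", c(`(Intercept)` = 1, Z = 3), c(`(Intercept)` = .1, Z = .3),
                 AIC = 20, p = 3, n = 100)
  f2 <- fake_fit("m2", c(`(Intercept)` = 2, Z = 1), c(`(Intercept)` = .1, Z = .2),
                 AIC = 22, p = 3, n = 100)
  rk <- rank_models(list(f1, f2))
  w <- exp(-rk$delta / 2); w <- w / sum(w)
  avg <- average_models(rk)
  z <- avg$coefficients[avg$coefficients$term == "Z", ]
  zbar <- w[1] * 3 + w[2] * 1
  expect_equal(z$estimate, zbar, tolerance = 1e-12)
  expect_equal(z$se,
               w[1] * sqrt(0.3^2 + (3 - zbar)^2) +
               w[2] * sqrt(0.2^2 + (1 - zbar)^2), tolerance = 1e-12)
})

test_that("back-transformed predictions stay within 0-100%", {
  ft <- simulate_feature_table(seed = 44)
  fits <- suppressWarnings(
    lapply(enumerate_models(c("DIFPREVIOUS", "VARIABLES")),
           fit_candidate, features = ft))
  avg <- average_models(rank_models(fits))
  pc <- prediction_curve(avg, list(DIFPREVIOUS = seq(-5, 40, 1),
                                   VARIABLES = c(10, 11, 12)))
  expect_true(all(pc$fit >= 0 & pc$fit <= 100))
  expect_true(all(pc$lwr >= 0 & pc$upr <= 100))
  expect_true(all(pc$upr >= pc$fit & pc$fit >= pc$lwr))
})
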