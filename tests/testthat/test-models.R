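test_that("fit_linear solves noiseless lines exactly", {
  d <- data.frame(pdff = 2 * c(0.5, 0.8, 1.0, 1.2) + 1,
                  ac = c(0.5, 0.8, 1.0, 1.2))
  fit <- fit_linear(d, "ac")
  expect_equal(fit$coefficients$betas, 2, tolerance = 1e-10)
  expect_equal(fit$coefficients$intercept, 1, tolerance = 1e-10)
  expect_equal(fit$rss, 0, tolerance = 1e-18)
  expect_equal(fit$n_params, 3L)

  dc <- data.frame(pdff = rep(7, 6), ac = runif(6))
  fitc <- fit_linear(dc, "ac")
  expect_equal(fitc$coefficients$betas, 0, tolerance = 1e-10)
  expect_equal(fitc$coefficients$intercept, 7, tolerance = 1e-10)
})

test_that("fit_linear flags collinear designs and short data", {
  d <- make_linear_cohort(20, seed = 2, noise = 1)
  d$bscd <- 2 * d$ac  # exactly collinear
  expect_error(fit_linear(d, c("ac", "bscd")), "collinear.*bscd")
  expect_error(fit_linear(d[1:3, ], c("ac", "bscd")), "complete rows")
})

test_that("univariable AC fit recovers the generating inverse-regression slope", {
  gen <- generate_cohort(default_params("training_like", n = 500, seed = 21))
  fit <- fit_linear(gen$cohort, "ac")
  expect_lt(abs(fit$coefficients$betas - 53.04) / 53.04, 0.10)
})

test_that("fit_exp recovers exponential coefficients from noiseless data", {
  d <- make_exp_data(50, b1 = 3, b2 = 2, b3 = 1, noise = 0, seed = 3,
                     ac_range = c(0, 1))
  fit <- fit_exp(d, "ac")
  expect_true(fit$converged)
  expect_equal(fit$coefficients$amplitude, 3, tolerance = 1e-6)
  expect_equal(unname(fit$coefficients$rates), 2, tolerance = 1e-6)
  expect_equal(fit$coefficients$offset, 1, tolerance = 1e-6)
  expect_equal(fit$n_params, 4L)
})

test_that("fit_exp handles the degenerate constant-outcome case", {
  d <- data.frame(pdff = rep(5, 10), ac = seq(0.5, 1.4, 0.1))
  fit <- fit_exp(d, "ac")
  pred <- predict(fit, d)
  expect_equal(pred, rep(5, 10), tolerance = 1e-6)
  expect_lt(fit$rss, 1e-10)
})

test_that("fit_exp rejects constant predictors and fits multivariable forms", {
  d <- make_exp_data(30, seed = 4)
  d$bscd <- 100
  expect_error(fit_exp(d, c("ac", "bscd")), "degenerate")
  set.seed(5)
  d$bscd <- rnorm(30, 100, 5)
  d$pdff <- 0.5 * exp(2 * d$ac + 0.03 * d$bscd) + 2
  fit <- fit_exp(d, c("ac", "bscd"))
  expect_true(fit$converged)
  expect_equal(unname(fit$coefficients$rates), c(2, 0.03), tolerance = 1e-4)
  expect_equal(fit$coefficients$amplitude, 0.5, tolerance = 1e-3)
})

test_that("predictions match a hand-rolled evaluation of the model formulas", {
  set.seed(6)
  rows <- data.frame(ac = runif(100, 0.6, 1.1), bscd = rnorm(100, 100, 8))
  lin <- fit_linear(make_linear_cohort(40, seed = 7, noise = 2), c("ac", "bscd"))
  by_hand <- lin$coefficients$betas[1] * rows$ac +
    lin$coefficients$betas[2] * rows$bscd + lin$coefficients$intercept
  expect_equal(predict(lin, rows), by_hand, tolerance = 1e-12)

  ex <- fit_exp(make_exp_data(40, noise = 0.5, seed = 8), "ac")
  by_hand_e <- ex$coefficients$amplitude *
    exp(ex$coefficients$rates[["ac"]] * rows$ac) + ex$coefficients$offset
  expect_equal(predict(ex, rows), by_hand_e, tolerance = 1e-12)
  expect_error(predict(lin, rows["ac"]), "bscd")
})

test_that("the Gaussian log-likelihood follows its closed form", {
  expect_equal(gaussian_loglik(10, 10), -5 * (log(2 * pi) + 1))
  # quadrupling rss at fixed n lowers LL by n/2 * log(4)
  expect_equal(gaussian_loglik(4, 12) - gaussian_loglik(16, 12), 6 * log(4))
  expect_identical(gaussian_loglik(0, 10), -Inf)
  # matches numeric maximization of the Gaussian likelihood over sigma
  set.seed(9)
  resid <- rnorm(25, 0, 2)
  rss <- sum(resid^2)
  num <- optimize(function(s) sum(dnorm(resid, 0, s, log = TRUE)),
                  c(0.1, 10), maximum = TRUE, tol = 1e-10)
  expect_equal(gaussian_loglik(rss, 25), num$objective, tolerance = 1e-6)
})

test_that("log-likelihood is strictly decreasing in rss at fixed n", {
  rss <- seq(0.5, 50, length.out = 30)
  ll <- vapply(rss, gaussian_loglik, numeric(1), n = 40)
  expect_true(all(diff(ll) < 0))
})

test_that("lr_test follows the chi-square reference distribution", {
  expect_equal(lr_test(-100, -100, df = 1)$p, 1)
  expect_equal(lr_test(-100, -100 + 3.841459 / 2, df = 1)$p, 0.05,
               tolerance = 1e-4)
  expect_equal(lr_test(-100, -99, df = 0)$p, 1)   # equal-size non-nested models
  expect_equal(lr_test(-99, -100, df = 2)$p, 1)   # negative statistic guard
  # Monte-Carlo tail oracle
  set.seed(10)
  draws <- rchisq(1e5, df = 2)
  stat <- 5.2
  mc <- mean(draws > stat)
  se <- sqrt(mc * (1 - mc) / 1e5)
  expect_lt(abs(lr_test(-100, -100 + stat / 2, df = 2)$p - mc), 3 * se)
})

test_that("linear rss is a local and nested minimum", {
  d <- make_linear_cohort(60, seed = 11, noise = 3)
  fit <- fit_linear(d, "ac")
  rss_of <- function(b, a) sum((d$pdff - b * d$ac - a)^2)
  base <- rss_of(fit$coefficients$betas, fit$coefficients$intercept)
  for (db in c(-1e-3, 1e-3)) {
    expect_gte(rss_of(fit$coefficients$betas + db, fit$coefficients$intercept), base)
    expect_gte(rss_of(fit$coefficients$betas, fit$coefficients$intercept + db), base)
  }
  # adding a predictor never increases rss
  fit2 <- fit_linear(d, c("ac", "bscd"))
  expect_lte(fit2$rss, fit$rss + 1e-10)
})

test_that("fit_exp matches or beats the linear fit on exponential-truth data", {
  d <- make_exp_data(120, b1 = 4, b2 = 1.2, b3 = 2, noise = 0.8, seed = 12)
  d$bscd <- rnorm(120, 100, 5)
  lin <- fit_linear(d, "ac")
  ex <- fit_exp(d, "ac")
  expect_lte(ex$rss, lin$rss + 1e-6)
})

test_that("linear prediction is affine-equivariant in the outcome", {
  d <- make_linear_cohort(40, seed = 13, noise = 2)
  f0 <- fit_linear(d, "ac")
  d2 <- d; d2$pdff <- d2$pdff + 7
  f1 <- fit_linear(d2, "ac")
  expect_equal(f1$coefficients$intercept, f0$coefficients$intercept + 7,
               tolerance = 1e-9)
  expect_equal(predict(f1, d), predict(f0, d) + 7, tolerance = 1e-9)
})

test_that("model files round-trip through the key-value format", {
  lin <- fit_linear(make_linear_cohort(30, seed = 14, noise = 1), c("ac", "bscd"))
  ex <- fit_exp(make_exp_data(30, noise = 0.3, seed = 15), "ac")
  path <- withr::local_tempfile(fileext = ".txt")
  for (fit in list(lin, ex)) {
    write_model(fit, path)
    back <- read_model(path)
    expect_equal(back$coefficients, fit$coefficients, tolerance = 1e-15)
    expect_identical(back$predictors, fit$predictors)
    expect_equal(back$loglik, fit$loglik, tolerance = 1e-12)
  }
  cm <- compound_model(lin, ex, 0.84, 105, "CAC")
  write_model(cm, path)
  back <- read_model(path)
  rows <- data.frame(ac = runif(10, 0.6, 1.1), bscd = rnorm(10, 100, 8))
  expect_equal(as.numeric(compound_predict(back, rows)),
               as.numeric(compound_predict(cm, rows)), tolerance = 1e-12)
})

test_that("selection_table mirrors the summary.lm statistics", {
  d <- make_linear_cohort(50, seed = 16, noise = 4)
  tab <- selection_table(d, c("ac", "bscd"))
  sm <- summary(lm(pdff ~ ac, data = d))
  row_ac <- tab[tab$model == "ac", ]
  expect_equal(row_ac$f_statistic, unname(sm$fstatistic[1]), tolerance = 1e-10)
  expect_equal(row_ac$r_squared, sm$r.squared, tolerance = 1e-10)
  expect_equal(row_ac$b, unname(coef(sm)["ac", 1]), tolerance = 1e-10)
  multi <- tab[tab$model == "multivariable", ]
  expect_true(multi$adjusted)
})
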