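test_that("pearson_eval matches the covariance formula and cor.test p", {
  set.seed(20)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    x <- rnorm(n); y <- 0.5 * x + rnorm(n)
    pe <- pearson_eval(x, y)
    r_direct <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(pe$r, r_direct, tolerance = 1e-10)
    expect_equal(pe$r_squared, r_direct^2, tolerance = 1e-10)
    tt <- r_direct * sqrt((n - 2) / (1 - r_direct^2))
    expect_equal(pe$p, 2 * pt(-abs(tt), n - 2), tolerance = 1e-10)
  }
})

test_that("pearson_eval handles identity, negation and degenerate inputs", {
  x <- rnorm(10)
  expect_equal(pearson_eval(x, x)$r, 1, tolerance = 1e-12)
  expect_lt(pearson_eval(x, x)$p, 1e-10)
  expect_equal(pearson_eval(x, -x)$r, -1, tolerance = 1e-12)
  expect_error(pearson_eval(rep(1, 10), x), "zero variance")
  expect_error(pearson_eval(x[1:2], x[1:2]), "at least 3")
})

test_that("icc_a1 matches an independent aov decomposition", {
  set.seed(21)
  for (i in 1:100) {
    n <- sample(5:15, 1)
    pred <- rnorm(n, 10, 4)
    ref <- pred + rnorm(n, sample(c(0, 2), 1), 1.5)
    expect_equal(icc_a1(pred, ref), icc_a1_aov(pred, ref), tolerance = 1e-10)
  }
})

test_that("icc_a1 penalizes bias while pearson does not", {
  set.seed(22)
  ref <- rnorm(30, 12, 6)
  expect_equal(icc_a1(ref, ref), 1, tolerance = 1e-12)
  shifted <- ref + 15
  expect_equal(pearson_eval(shifted, ref)$r, 1, tolerance = 1e-12)
  expect_lt(icc_a1(shifted, ref), 0.5)
  expect_error(icc_a1(rep(3, 10), rep(3, 10)), "degenerate")
})

test_that("icc_a1 never exceeds the pearson-based upper bound", {
  set.seed(23)
  for (i in 1:50) {
    n <- sample(5:30, 1)
    a <- rnorm(n); b <- rnorm(n, 1, 2) + 0.6 * a
    expect_lte(icc_a1(a, b), abs(cor(a, b)) + 0.01)
  }
})

test_that("pearson is invariant to positive affine maps, icc is not", {
  set.seed(24)
  a <- rnorm(25, 10, 3); b <- a + rnorm(25, 0, 1)
  expect_equal(pearson_eval(2 * a + 5, b)$r, pearson_eval(a, b)$r,
               tolerance = 1e-12)
  expect_gt(abs(icc_a1(2 * a + 5, b) - icc_a1(a, b)), 0.05)
})

test_that("bland_altman computes bias and 1.96-sd limits", {
  a <- c(1, 2, 3, 4)
  res <- bland_altman(a, a)
  expect_equal(c(res$bias, res$loa_low, res$loa_high), c(0, 0, 0))
  res2 <- bland_altman(a + 0.5, a)
  expect_equal(res2$bias, 0.5)
  expect_equal(res2$loa_low, 0.5)  # zero-width limits for a constant offset
  set.seed(25)
  d <- rnorm(20, 1, 2); b <- rnorm(20, 10, 5)
  res3 <- bland_altman(b + d, b)
  expect_equal(res3$bias, mean(d), tolerance = 1e-12)
  expect_equal(res3$loa_high - res3$bias, 1.96 * sd(d), tolerance = 1e-12)
})

test_that("limits of agreement bracket ~95% of gaussian differences", {
  set.seed(26)
  a <- rnorm(1e4, 10, 3)
  b <- a + rnorm(1e4, 0.5, 1)
  res <- bland_altman(a, b)
  inside <- mean(res$diffs >= res$loa_low & res$diffs <= res$loa_high)
  expect_gt(inside, 0.945)
  expect_lt(inside, 0.955)
})

test_that("grade-stratified evaluation equals manual masking", {
  gen <- generate_cohort(default_params("test_like", n = 120, seed = 27))
  co <- gen$cohort
  pred <- predict(fit_linear(co, c("ac", "bscd")), co)
  rep_lh <- evaluate_by_grade(pred, co, "low_high")
  grade <- classify_steatosis(co$pdff)
  low <- grade %in% c("S0", "S1")
  expect_equal(rep_lh$pearson_r[rep_lh$subgroup == "S0+S1"],
               cor(pred[low], co$pdff[low]), tolerance = 1e-12)
  expect_equal(rep_lh$icc[rep_lh$subgroup == "S2+S3"],
               icc_a1(pred[!low], co$pdff[!low]), tolerance = 1e-12)
  # grouping = "all" consistent with the direct statistics
  rep_all <- evaluate_by_grade(pred, co, "all")
  expect_equal(rep_all$pearson_r, pearson_eval(pred, co$pdff)$r, tolerance = 1e-12)
  expect_equal(rep_all$icc, icc_a1(pred, co$pdff), tolerance = 1e-12)
})

test_that("under-filled grade groups are flagged not-evaluable", {
  co <- as_cohort(data.frame(subject_id = letters[1:6], split = "train",
                             ac = seq(0.6, 1.1, 0.1), bscd = 95 + 1:6,
                             pdff = c(1, 2, 3, 4, 4.5, 2.5)))  # all S0
  pred <- co$pdff + 0.1
  rep <- evaluate_by_grade(pred, co, "low_high")
  expect_false(rep$evaluable[rep$subgroup == "S2+S3"])
  expect_true(is.na(rep$icc[rep$subgroup == "S2+S3"]))
  per <- evaluate_by_grade(pred, co, "per_grade")
  expect_true(per$evaluable[per$subgroup == "S0"])
  expect_false(any(per$evaluable[per$subgroup != "S0"]))
})

test_that("bonferroni decisions use alpha/m and never beat raw decisions", {
  expect_true(bonferroni_adjust(0.049, m = 1)$significant)
  expect_false(bonferroni_adjust(0.01, m = 6)$significant)  # 0.01 > 0.05/6
  set.seed(28)
  for (i in 1:20) {
    p <- runif(sample(3:12, 1))
    adj <- bonferroni_adjust(p)
    expect_lte(sum(adj$significant), sum(p < 0.05))
  }
})

test_that("repeated k-fold training is deterministic and refits on full data", {
  d <- make_linear_cohort(45, seed = 29, noise = 3)
  cv <- cv_spec(folds = 3, repeats = 5, seed = 123)
  a <- repeated_kfold_train(d, "linear", "ac", cv)
  b <- repeated_kfold_train(d, "linear", "ac", cv)
  expect_identical(a$cv, b$cv)
  expect_equal(a$fit$coefficients, fit_linear(d, "ac")$coefficients,
               tolerance = 1e-12)
  c2 <- repeated_kfold_train(d, "linear", "ac", cv_spec(3, 5, seed = 124))
  expect_false(identical(a$cv, c2$cv))
})

test_that("leave-one-out folds predict noiseless linear data exactly", {
  d <- make_linear_cohort(6, seed = 30, noise = 0)
  res <- repeated_kfold_train(d, "linear", "ac", cv_spec(folds = 6, repeats = 1,
                                                         seed = 1))
  expect_equal(unname(res$cv_summary["rmse"]), 0, tolerance = 1e-9)
})

test_that("held-out error shows the optimism gap against in-sample error", {
  optimism_ok <- 0
  for (s in 1:20) {
    d <- make_linear_cohort(36, seed = 100 + s, noise = 6)
    res <- repeated_kfold_train(d, "linear", "ac", cv_spec(3, 2, seed = s))
    in_sample_rmse <- sqrt(res$fit$rss / res$fit$n)
    if (res$cv_summary["rmse"] >= in_sample_rmse) optimism_ok <- optimism_ok + 1
  }
  expect_gte(optimism_ok, 16)
})
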