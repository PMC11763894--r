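# Independent oracles and small data builders shared across the test files.

# noiseless / noisy linear cohort: pdff = slope*ac + intercept + noise
make_linear_cohort <- function(n, seed = 1, slope = 20, intercept = 2,
                               noise = 0, ac_range = c(0.6, 1.1)) {
  set.seed(seed)
  ac <- runif(n, ac_range[1], ac_range[2])
  bscd <- rnorm(n, 100, 8)
  pdff <- slope * ac + intercept + rnorm(n, 0, noise)
  data.frame(pdff = pmin(pmax(pdff, 0), 100), ac = ac, bscd = bscd)
}

# exponential-truth data: pdff = b1*exp(b2*ac) + b3 + noise
make_exp_data <- function(n, b1 = 1.5, b2 = 2.8, b3 = 1, noise = 0,
                          seed = 1, ac_range = c(0.55, 1.15)) {
  set.seed(seed)
  ac <- runif(n, ac_range[1], ac_range[2])
  data.frame(pdff = b1 * exp(b2 * ac) + b3 + rnorm(n, 0, noise), ac = ac)
}

# two-sided Fisher p by exhaustive enumeration of the conditional
# (hypergeometric) distribution, minimum-likelihood rule
fisher_p_enum <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c
  support <- max(0, k - m2):min(k, m1)
  probs <- dhyper(support, m1, m2, k)
  p_obs <- dhyper(a, m1, m2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# conditional-MLE odds ratio by matching the noncentral hypergeometric mean
fisher_or_cmle_enum <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c
  support <- max(0, k - m2):min(k, m1)
  if (a == min(support)) return(0)
  if (a == max(support)) return(Inf)
  cond_mean <- function(log_psi) {
    w <- lchoose(m1, support) + lchoose(m2, k - support) + support * log_psi
    w <- exp(w - max(w))
    sum(support * w) / sum(w) - a
  }
  exp(uniroot(cond_mean, c(-30, 30), tol = 1e-12)$root)
}

# ICC(A,1) through an independent aov() two-way decomposition
icc_a1_aov <- function(pred, ref) {
  n <- length(pred)
  long <- data.frame(value = c(pred, ref),
                     subject = factor(rep(seq_len(n), 2)),
                     method = factor(rep(c("pred", "ref"), each = n)))
  ms <- summary(aov(value ~ subject + method, data = long))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + mse + (2 / n) * (msc - mse))
}

# brute-force compound scoring used as grid-search oracle
compound_score_brute <- function(rows, lin_fit, non_fit, t_ac, t_bscd) {
  pred <- numeric(nrow(rows))
  for (i in seq_len(nrow(rows))) {
    use_nonlin <- rows$ac[i] >= t_ac && rows$bscd[i] >= t_bscd
    fit <- if (use_nonlin) non_fit else lin_fit
    pred[i] <- predict(fit, rows[i, , drop = FALSE])
  }
  c(r2 = cor(pred, rows$pdff)^2, icc = icc_a1(pred, rows$pdff))
}

plateau_train_test <- function(seed, n = 300) {
  tr_params <- default_params("plateau_stress", n = n, seed = seed)
  te_params <- default_params("plateau_stress", n = n, seed = seed + 1000L)
  te_params$split <- "test"
  list(train = generate_cohort(tr_params)$cohort,
       test = generate_cohort(te_params)$cohort)
}
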