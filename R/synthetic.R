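# Seeded synthetic-cohort generator. The forward model follows the causal
# direction -- liver fat drives the acoustics: a steatosis grade is sampled
# from a mixture, PDFF from a truncated normal inside that grade's band, and
# AC / BSC-D from a (linear or saturating) link on PDFF plus Gaussian noise.
# Link coefficients are calibrated analytically so the *inverse* regressions
# (PDFF on AC, PDFF on BSC-D) recover configured slope / R-squared targets in
# expectation, together with the configured marginal means.

pdff_cutoffs <- function(pdff_max = 45) c(0, 5, 15, 20, pdff_max)

# moments of N(mu, sd^2) truncated to [a, b)
trunc_norm_moments <- function(mu, sd, a, b) {
  al <- (a - mu) / sd; be <- (b - mu) / sd
  Z <- stats::pnorm(be) - stats::pnorm(al)
  m <- mu + sd * (stats::dnorm(al) - stats::dnorm(be)) / Z
  v <- sd^2 * (1 + (al * stats::dnorm(al) - be * stats::dnorm(be)) / Z -
                 ((stats::dnorm(al) - stats::dnorm(be)) / Z)^2)
  c(mean = m, var = v)
}

# mean and variance of the PDFF grade mixture
pdff_mixture_moments <- function(grade_weights, pdff_bands, pdff_max = 45) {
  cuts <- pdff_cutoffs(pdff_max)
  M <- vapply(1:4, function(g) {
    trunc_norm_moments(pdff_bands[[g]][1], pdff_bands[[g]][2],
                       cuts[g], cuts[g + 1])
  }, numeric(2))
  m <- sum(grade_weights * M["mean", ])
  v <- sum(grade_weights * (M["var", ] + M["mean", ]^2)) - m^2
  c(mean = m, var = v)
}

# Solve a linear link x = a0 + a1*pdff + noise such that regressing pdff on x
# recovers `slope` and `r2`, and the marginal mean of x is `mean_x`:
#   a1 = r2/slope,  sd^2 = a1*Vp*(1/slope - a1),  a0 = mean_x - a1*Ep.
calibrate_linear_link <- function(slope, r2, mean_x, pdff_mean, pdff_var) {
  stopifnot(slope > 0, r2 > 0, r2 < 1)
  a1 <- r2 / slope
  sd <- sqrt(a1 * pdff_var * (1 / slope - a1))
  list(type = "linear", a0 = mean_x - a1 * pdff_mean, a1 = a1, sd = sd)
}

#' Synthetic-cohort parameters
#'
#' Bundles everything [generate_cohort()] needs. Defaults for the individual
#' pieces are supplied by [default_params()]; use this constructor directly
#' only for custom experiments.
#'
#' @param n cohort size, >= 1.
#' @param grade_weights probabilities over S0..S3, summing to 1.
#' @param pdff_bands list of 4 `c(location, scale)` pairs, one per grade, for
#'   the truncated-normal PDFF draw inside each grade band.
#' @param ac_link list: `type = "linear"` with `a0`, `a1`, `sd`, or
#'   `type = "plateau"` with `a0`, `a1`, `scale`, `sd`
#'   (`ac = a0 + a1*(1 - exp(-pdff/scale)) + noise`).
#' @param bscd_link list: `b0`, `b1`, `sd` (linear).
#' @param usff list: `enabled` flag and noise `sd` (percent) for the emulated
#'   vendor fat fraction.
#' @param covariates list of `c(mean, sd)` for `bmi`, `sld`, `ls`, `age`, and
#'   `p_female`; plumbing columns sampled independently of PDFF.
#' @param resid_cor correlation between AC and BSC-D noise (default 0).
#' @param split split label written to every row ("train" or "test").
#' @param pdff_max upper PDFF truncation for grade S3 (percent).
#' @param seed integer master seed; per-stage substreams are derived from it
#'   (stage k reseeds with `(seed mod 2^27)*8 + k`), so enabling later
#'   columns never perturbs earlier ones.
#' @return list of class `qus_synth_params`.
#' @export
synth_params <- function(n, grade_weights, pdff_bands, ac_link, bscd_link,
                         usff = list(enabled = TRUE, sd = 1.2),
                         covariates = NULL, resid_cor = 0,
                         split = "train", pdff_max = 45, seed = 1L) {
  stopifnot(n >= 1, length(grade_weights) == 4, all(grade_weights >= 0),
            abs(sum(grade_weights) - 1) < 1e-8,
            length(pdff_bands) == 4,
            all(vapply(pdff_bands, function(b) b[2] > 0, logical(1))),
            ac_link$type %in% c("linear", "plateau"), ac_link$sd > 0,
            bscd_link$sd > 0, abs(resid_cor) <= 1,
            split %in% c("train", "test"), pdff_max > 20)
  if (is.null(covariates)) {
    covariates <- list(bmi = c(29.8, 4.18), sld = c(2.16, 0.51),
                       ls = c(7.59, 3.4), age = c(57.3, 13.6),
                       p_female = 0.43)
  }
  structure(list(n = as.integer(n), grade_weights = grade_weights,
                 pdff_bands = pdff_bands, ac_link = ac_link,
                 bscd_link = bscd_link, usff = usff, covariates = covariates,
                 resid_cor = resid_cor, split = split, pdff_max = pdff_max,
                 seed = as.integer(seed)),
            class = "qus_synth_params")
}

#' Default generator profiles
#'
#' Three ready-made parameter sets:
#' * `training_like`: grade mix 16/16/12/16 over S0..S3, linear AC and BSC-D
#'   links calibrated so the inverse regressions recover slope 53.04 /
#'   R2 0.533 (PDFF on AC) and slope 0.573 / R2 0.265 (PDFF on BSC-D) with
#'   marginal means AC 0.84 dB/cm/MHz and BSC-D 100.69.
#' * `test_like`: grade mix 3/23/12/19, same calibrated links, `split =
#'   "test"`, covariate marginals of a prospective screening population.
#' * `plateau_stress`: same grade mix as training but a saturating AC link
#'   `ac = 0.60 + 0.50*(1 - exp(-pdff/10)) + N(0, 0.02)`, which flattens in
#'   high-grade steatosis and rewards switching to a nonlinear model.
#'
#' @param profile one of `"training_like"`, `"test_like"`,
#'   `"plateau_stress"`.
#' @param n cohort size (defaults: 60 train-like, 57 test-like).
#' @param seed master seed.
#' @return a [synth_params()] object.
#' @export
default_params <- function(profile = c("training_like", "test_like",
                                       "plateau_stress"),
                           n = NULL, seed = 1L) {
  profile <- match.arg(profile)
  bands <- list(c(3, 1.8), c(9, 3.5), c(17.5, 2.5), c(26, 7))
  weights <- switch(profile,
                    test_like = c(3, 23, 12, 19) / 57,
                    c(16, 16, 12, 16) / 60)
  mm <- unname(pdff_mixture_moments(weights, bands))
  bscd_link <- calibrate_linear_link(0.573, 0.265, 100.69, mm[1], mm[2])
  names(bscd_link) <- c("type", "b0", "b1", "sd")
  ac_link <- if (profile == "plateau_stress") {
    list(type = "plateau", a0 = 0.60, a1 = 0.50, scale = 10, sd = 0.02)
  } else {
    calibrate_linear_link(53.04, 0.533, 0.84, mm[1], mm[2])
  }
  covariates <- if (profile == "test_like") {
    list(bmi = c(30.57, 3.68), sld = c(2.41, 0.47), ls = c(5.38, 3.03),
         age = c(50.3, 13.2), p_female = 0.456)
  } else {
    list(bmi = c(29.8, 4.18), sld = c(2.16, 0.51), ls = c(7.59, 3.4),
         age = c(57.3, 13.6), p_female = 0.43)
  }
  if (is.null(n)) n <- if (profile == "test_like") 57L else 60L
  synth_params(n = n, grade_weights = weights, pdff_bands = bands,
               ac_link = ac_link, bscd_link = bscd_link,
               covariates = covariates,
               split = if (profile == "test_like") "test" else "train",
               seed = seed)
}

# inverse-CDF truncated-normal sampler; output clamped inside [a, b) so that
# grading always round-trips to the sampled grade
rtrunc_norm <- function(n, mu, sd, a, b) {
  lo <- stats::pnorm((a - mu) / sd)
  hi <- stats::pnorm((b - mu) / sd)
  x <- mu + sd * stats::qnorm(stats::runif(n, lo, hi))
  pmin(pmax(x, a), b - 1e-9)
}

substream_seed <- function(seed, stage) (seed %% 134217728L) * 8L + stage

with_stage_seed <- function(seed, stage, expr) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(substream_seed(seed, stage))
  expr
}

#' Generate a synthetic QUS cohort
#'
#' Samples, in seeded substreams: (1) a steatosis grade per subject, (2) a
#' PDFF value from the grade's truncated band (so [classify_steatosis()]
#' reproduces the sampled grade exactly), (3-4) AC and BSC-D from the
#' configured links plus Gaussian noise, (5) an optional emulated USFF (the
#' in-sample linear projection of PDFF on AC and BSC-D plus noise, clipped
#' to \[0, 100\]), and (6) independent clinical covariates. Identical
#' parameters reproduce the cohort exactly.
#'
#' @param params a [synth_params()] object.
#' @return list of class `qus_syncohort`: `cohort` (a `qus_cohort`) and
#'   `truth` (the parameters plus per-subject latent values: sampled grade
#'   and the noise-free AC / BSC-D link values).
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "qus_synth_params"))
  n <- params$n
  seed <- params$seed
  cuts <- pdff_cutoffs(params$pdff_max)

  grade <- with_stage_seed(seed, 1L,
    sample.int(4, n, replace = TRUE, prob = params$grade_weights))
  pdff <- with_stage_seed(seed, 2L, {
    u <- numeric(n)
    for (g in 1:4) {
      idx <- which(grade == g)
      if (length(idx)) {
        u[idx] <- rtrunc_norm(length(idx), params$pdff_bands[[g]][1],
                              params$pdff_bands[[g]][2], cuts[g], cuts[g + 1])
      }
    }
    u
  })

  acl <- params$ac_link
  ac_mu <- if (acl$type == "linear") acl$a0 + acl$a1 * pdff else
    acl$a0 + acl$a1 * (1 - exp(-pdff / acl$scale))
  z_ac <- with_stage_seed(seed, 3L, stats::rnorm(n))
  ac <- pmax(ac_mu + acl$sd * z_ac, 1e-6)

  bcl <- params$bscd_link
  bscd_mu <- bcl$b0 + bcl$b1 * pdff
  z2 <- with_stage_seed(seed, 4L, stats::rnorm(n))
  rho <- params$resid_cor
  bscd <- pmax(bscd_mu + bcl$sd * (rho * z_ac + sqrt(1 - rho^2) * z2), 1e-6)

  usff <- rep(NA_real_, n)
  if (isTRUE(params$usff$enabled)) {
    proj <- stats::lm.fit(cbind(1, ac, bscd), pdff)$fitted.values
    z_u <- with_stage_seed(seed, 5L, stats::rnorm(n))
    usff <- pmin(pmax(proj + params$usff$sd * z_u, 0), 100)
  }

  cov <- params$covariates
  covs <- with_stage_seed(seed, 6L, {
    list(bmi = pmax(stats::rnorm(n, cov$bmi[1], cov$bmi[2]), 15),
         sld = pmax(stats::rnorm(n, cov$sld[1], cov$sld[2]), 0.5),
         ls = pmax(stats::rnorm(n, cov$ls[1], cov$ls[2]), 1),
         age = round(pmin(pmax(stats::rnorm(n, cov$age[1], cov$age[2]), 18), 95)),
         sex = ifelse(stats::runif(n) < cov$p_female, "female", "male"))
  })

  cohort <- as_cohort(
    data.frame(subject_id = sprintf("%s%04d", substr(params$split, 1, 2), seq_len(n)),
               split = params$split, ac = ac, bscd = bscd, pdff = pdff,
               usff = usff, bmi = covs$bmi, sld = covs$sld, ls = covs$ls,
               age = covs$age, sex = covs$sex),
    provenance = sprintf("synthetic seed=%d n=%d ac_link=%s", seed, n, acl$type))
  structure(list(cohort = cohort,
                 truth = list(params = params,
                              grade = factor(c("S0", "S1", "S2", "S3")[grade],
                                             levels = c("S0", "S1", "S2", "S3")),
                              ac_latent = ac_mu, bscd_latent = bscd_mu)),
            class = "qus_syncohort")
}

#' Generate a paired train/test synthetic study
#'
#' Convenience wrapper reproducing the study layout: a balanced-grade
#' training cohort and a prospectively-skewed test cohort drawn with
#' distinct seeds, concatenated into one cohort table.
#'
#' @param seed master seed; train uses `seed`, test `seed + 500000`.
#' @param n_train,n_test cohort sizes (defaults 60 / 57).
#' @param train_profile,test_profile generator profiles, see
#'   [default_params()].
#' @return a `qus_cohort` with both splits.
#' @export
generate_study <- function(seed = 1L, n_train = 60L, n_test = 57L,
                           train_profile = "training_like",
                           test_profile = "test_like") {
  tr <- generate_cohort(default_params(train_profile, n = n_train, seed = seed))
  te_params <- default_params(test_profile, n = n_test, seed = seed + 500000L)
  te_params$split <- "test"
  te <- generate_cohort(te_params)
  df <- rbind(as.data.frame(tr$cohort), as.data.frame(te$cohort))
  df$subject_id <- c(paste0("tr", sprintf("%04d", seq_len(n_train))),
                     paste0("te", sprintf("%04d", seq_len(n_test))))
  as_cohort(df, provenance = sprintf("synthetic study seed=%d", seed))
}

#' Write a sidecar file with the generator parameters
#'
#' Key-value text capture of a [synth_params()] object, sufficient for exact
#' regeneration.
#'
#' @param params a `qus_synth_params`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "qus_synth_params"))
  flat <- unlist(params)
  writeLines(paste0(names(flat), "=", vapply(flat, as.character, character(1))),
             path)
  invisible(path)
}
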