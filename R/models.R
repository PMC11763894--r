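# Fat-fraction regression models. Outcome is always MRI-PDFF (percent).
# Linear:      pdff = b1.x1 + ... + bp.xp + intercept          (OLS, stats::lm)
# Exponential: pdff = b1 * exp(b21.x1 + ... + b2p.xp) + b3     (NLLS)
# The exponential "additive" form pdff = sum_j b1j*exp(b2j.xj) + b3 is kept
# behind `form = "additive"` for sensitivity analyses.

valid_predictors <- c("ac", "bscd", "bmi", "sld")

check_predictors <- function(predictors) {
  if (!length(predictors)) stop("empty predictor set", call. = FALSE)
  if (anyDuplicated(predictors)) stop("duplicate predictors", call. = FALSE)
  unknown <- setdiff(predictors, valid_predictors)
  if (length(unknown)) {
    stop("unknown predictor(s): ", paste(unknown, collapse = ", "),
         "; allowed: ", paste(valid_predictors, collapse = ", "), call. = FALSE)
  }
  predictors
}

model_frame <- function(rows, predictors, outcome = "pdff") {
  missing_cols <- setdiff(c(predictors, outcome), names(rows))
  if (length(missing_cols)) {
    stop("column(s) absent from data: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- as.data.frame(rows)[c(outcome, predictors)]
  df[stats::complete.cases(df), , drop = FALSE]
}

#' Gaussian maximum-likelihood log-likelihood from a residual sum of squares
#'
#' `LL = -n/2 * (log(2*pi) + log(rss/n) + 1)`, the Gaussian log-likelihood
#' profiled over the error variance (MLE `sigma^2 = rss/n`). Used to compare
#' fitted fat-fraction models by likelihood ratio. `rss = 0` yields `-Inf`.
#'
#' @param rss residual sum of squares (percent squared), or a fit object
#'   from [fit_linear()] / [fit_exp()].
#' @param n number of observations (ignored when `rss` is a fit).
#' @return log-likelihood (natural log scale).
#' @export
gaussian_loglik <- function(rss, n) {
  if (inherits(rss, "qus_fit")) {
    n <- rss$n
    rss <- rss$rss
  }
  stopifnot(is.numeric(rss), rss >= 0, n > 0)
  if (rss == 0) return(-Inf)
  -n / 2 * (log(2 * pi) + log(rss / n) + 1)
}

new_qus_fit <- function(model_type, form, predictors, coefficients, n, rss,
                        n_params, converged, extra = list()) {
  fit <- c(list(model_type = model_type, form = form, predictors = predictors,
                coefficients = coefficients, n = n, rss = rss,
                loglik = gaussian_loglik(rss, n), n_params = n_params,
                converged = converged), extra)
  class(fit) <- "qus_fit"
  fit
}

#' Fit a linear fat-fraction model by ordinary least squares
#'
#' Fits `pdff = b1.X1 + ... + intercept` on the complete rows of `rows`.
#' Alongside the coefficients, the result carries the per-model F statistic,
#' R-squared and adjusted R-squared, and a per-predictor coefficient table,
#' as used for variable selection.
#'
#' @param rows cohort rows (a `qus_cohort` or data.frame) containing `pdff`
#'   and the predictor columns.
#' @param predictors character vector, ordered subset of
#'   `c("ac", "bscd", "bmi", "sld")`.
#' @return a `qus_fit` with `model_type = "linear"`. `n_params` counts the
#'   error variance (univariable model: 3).
#' @export
fit_linear <- function(rows, predictors) {
  predictors <- check_predictors(predictors)
  df <- model_frame(rows, predictors)
  n_params <- length(predictors) + 2L  # betas + intercept + sigma
  if (nrow(df) <= n_params) {
    stop("need more than ", n_params, " complete rows, got ", nrow(df),
         call. = FALSE)
  }
  fml <- stats::as.formula(paste("pdff ~", paste(predictors, collapse = " + ")))
  fit <- stats::lm(fml, data = df)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("rank-deficient design; collinear predictor(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  }
  sm <- suppressWarnings(summary(fit))  # noiseless fits warn about perfect fit
  new_qus_fit(
    model_type = "linear", form = "linear", predictors = predictors,
    coefficients = list(betas = unname(cf[predictors]),
                        intercept = unname(cf["(Intercept)"])),
    n = nrow(df), rss = sum(stats::residuals(fit)^2), n_params = n_params,
    converged = TRUE,
    extra = list(
      r_squared = sm$r.squared, adj_r_squared = sm$adj.r.squared,
      fstatistic = if (!is.null(sm$fstatistic)) unname(sm$fstatistic[1]) else NA_real_,
      coef_table = sm$coefficients))
}

# deterministic multistart initial values for the exponential fit, built from
# moment-based guesses on centred predictors (log-linear regression of
# y - b3 on X); no randomness involved
exp_starts <- function(y, Xc, form) {
  rng <- diff(range(y))
  b3_cands <- unique(c(min(y) - 0.05 * max(rng, 1), 0, min(y) - stats::sd(y)))
  starts <- list()
  for (b3 in b3_cands) {
    z <- y - b3
    if (any(z <= 0)) z <- pmax(z, 1e-6)
    lf <- stats::lm.fit(cbind(1, Xc), log(z))
    b1 <- exp(lf$coefficients[1])
    b2 <- lf$coefficients[-1]
    for (scl in c(1, 0.5, 2)) {
      if (form == "shared") {
        starts[[length(starts) + 1L]] <- c(b1, b2 * scl, b3)
      } else {
        p <- ncol(Xc)
        starts[[length(starts) + 1L]] <- c(rep(b1 / p, p), b2 * scl, b3)
      }
    }
  }
  starts
}

exp_residual_fun <- function(y, Xc, form) {
  p <- ncol(Xc)
  if (form == "shared") {
    function(theta) {
      y - (theta[1] * exp(drop(Xc %*% theta[2:(p + 1)])) + theta[p + 2])
    }
  } else {
    function(theta) {
      amp <- theta[seq_len(p)]
      rate <- theta[p + seq_len(p)]
      y - (drop(exp(Xc * rep(rate, each = nrow(Xc))) %*% amp) + theta[2 * p + 1])
    }
  }
}

#' Fit an exponential fat-fraction model by nonlinear least squares
#'
#' Fits `pdff = b1 * exp(b2.X) + b3` (one amplitude `b1`, one rate
#' coefficient per predictor, one offset `b3`) by Levenberg-Marquardt least
#' squares with a deterministic multistart: starting values come from a grid
#' of moment-based guesses (offset candidates from `min(y)`; amplitude and
#' rates from a log-linear regression of `y - b3` on the predictors), so
#' fitting involves no randomness. Predictors are centred internally and the
#' amplitude back-transformed, which keeps the exponent well-scaled for
#' predictors like BSC-D (~100).
#'
#' @inheritParams fit_linear
#' @param init optional numeric start vector on the original scale
#'   (`c(b1, rates, b3)` for the shared form), tried in addition to the grid.
#' @param form `"shared"` (default): one amplitude, exponent is a linear
#'   combination of predictors. `"additive"`: one amplitude and rate per
#'   predictor, summed.
#' @return a `qus_fit` with `model_type = "exp"`; `converged = FALSE` (never
#'   a silent error) when no start converges. `n_params` counts the error
#'   variance (univariable shared model: 4).
#' @export
fit_exp <- function(rows, predictors, init = NULL, form = c("shared", "additive")) {
  form <- match.arg(form)
  predictors <- check_predictors(predictors)
  df <- model_frame(rows, predictors)
  p <- length(predictors)
  n_coef <- if (form == "shared") p + 2L else 2L * p + 1L
  n_params <- n_coef + 1L  # + sigma
  if (nrow(df) <= n_params) {
    stop("need more than ", n_params, " complete rows, got ", nrow(df),
         call. = FALSE)
  }
  X <- as.matrix(df[predictors])
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("degenerate (constant) predictor(s): ",
         paste(predictors[sds == 0], collapse = ", "), call. = FALSE)
  }
  centers <- colMeans(X)
  Xc <- sweep(X, 2, centers)
  y <- df$pdff

  resid_fun <- exp_residual_fun(y, Xc, form)
  starts <- exp_starts(y, Xc, form)
  if (!is.null(init)) {
    stopifnot(length(init) == n_coef)
    ic <- init
    if (form == "shared") {  # original-scale init -> centred parameterization
      ic[1] <- init[1] * exp(sum(init[2:(p + 1)] * centers))
    } else {
      ic[seq_len(p)] <- init[seq_len(p)] * exp(init[p + seq_len(p)] * centers)
    }
    starts <- c(list(ic), starts)
  }

  best <- NULL
  converged <- FALSE
  for (st in starts) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-10, ptol = 1e-10)),
      error = function(e) NULL)
    if (is.null(res)) next
    ok <- res$info %in% 1:4
    rss <- sum(res$fvec^2)
    if (is.null(best) || (ok && !converged) ||
        (ok == converged && rss < best$rss - 1e-12)) {
      best <- list(par = res$par, rss = rss)
      converged <- converged || ok
    }
  }
  if (is.null(best)) stop("all NLLS starts failed", call. = FALSE)

  theta <- best$par
  if (form == "shared") {
    rate <- theta[2:(p + 1)]
    coefficients <- list(
      amplitude = unname(theta[1] * exp(-sum(rate * centers))),  # original scale
      rates = stats::setNames(rate, predictors),
      offset = unname(theta[p + 2]))
  } else {
    rate <- theta[p + seq_len(p)]
    coefficients <- list(
      amplitude = stats::setNames(theta[seq_len(p)] * exp(-rate * centers), predictors),
      rates = stats::setNames(rate, predictors),
      offset = unname(theta[2 * p + 1]))
  }
  fitted <- y - resid_fun(theta)
  new_qus_fit(
    model_type = "exp", form = form, predictors = predictors,
    coefficients = coefficients, n = nrow(df), rss = best$rss,
    n_params = n_params, converged = converged,
    extra = list(r_squared = if (stats::sd(fitted) > 0 && stats::sd(y) > 0)
      stats::cor(fitted, y)^2 else NA_real_))
}

#' Predict fat fraction from a fitted model
#'
#' Pointwise application of the model formula; predictions are not clipped
#' to \[0, 100\].
#'
#' @param object a `qus_fit`.
#' @param newdata rows containing the model's predictor columns.
#' @param ... unused.
#' @return numeric vector of predicted fat fractions (percent).
#' @export
predict.qus_fit <- function(object, newdata, ...) {
  missing_cols <- setdiff(object$predictors, names(newdata))
  if (length(missing_cols)) {
    stop("predictor column(s) absent: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  X <- as.matrix(as.data.frame(newdata)[object$predictors])
  cf <- object$coefficients
  if (object$model_type == "linear") {
    unname(drop(X %*% cf$betas) + cf$intercept)
  } else if (object$form == "shared") {
    unname(cf$amplitude * exp(drop(X %*% cf$rates)) + cf$offset)
  } else {
    unname(drop(exp(X * rep(cf$rates, each = nrow(X))) %*% cf$amplitude) + cf$offset)
  }
}

#' Likelihood-ratio comparison of two fitted models
#'
#' `statistic = 2 * (ll_full - ll_reduced)`, referred to an upper-tail
#' chi-square with `df` degrees of freedom. For `df = 0` or a negative
#' statistic the p-value is reported as 1 — the mechanical comparison used
#' for non-nested model pairs with equal parameter counts, where the LR
#' cannot discriminate.
#'
#' @param ll_reduced,ll_full log-likelihoods (or `qus_fit` objects).
#' @param df degrees of freedom, `>= 0`; defaults to the difference in
#'   parameter counts when both arguments are fits.
#' @return list of class `qus_lr`: `statistic`, `df`, `p`.
#' @export
lr_test <- function(ll_reduced, ll_full, df = NULL) {
  if (inherits(ll_reduced, "qus_fit") && inherits(ll_full, "qus_fit") &&
      is.null(df)) {
    df <- abs(ll_full$n_params - ll_reduced$n_params)
  }
  if (inherits(ll_reduced, "qus_fit")) ll_reduced <- ll_reduced$loglik
  if (inherits(ll_full, "qus_fit")) ll_full <- ll_full$loglik
  stopifnot(is.numeric(df), df >= 0, df == round(df))
  statistic <- 2 * (ll_full - ll_reduced)
  p <- if (df == 0 || statistic < 0) 1 else
    stats::pchisq(statistic, df = df, lower.tail = FALSE)
  structure(list(statistic = statistic, df = as.integer(df), p = p),
            class = "qus_lr")
}

#' Variable-selection table of simple linear regressions
#'
#' One multivariable linear regression of PDFF on all supplied predictors,
#' plus one univariable regression per predictor; reports the F statistic,
#' first-order coefficient and (adjusted) R-squared for each, the layout
#' used to screen clinical and ultrasound covariates.
#'
#' @param rows cohort rows with `pdff` and the predictor columns.
#' @param predictors predictors to screen (default AC and BSC-D).
#' @return data.frame with one row per model.
#' @export
selection_table <- function(rows, predictors = c("ac", "bscd")) {
  rows_of <- function(label, fit, adjusted) {
    b <- fit$coefficients$betas[1]
    data.frame(model = label, f_statistic = fit$fstatistic, b = b,
               r_squared = if (adjusted) fit$adj_r_squared else fit$r_squared,
               adjusted = adjusted,
               p = stats::pf(fit$fstatistic, length(fit$predictors),
                             fit$n - length(fit$predictors) - 1,
                             lower.tail = FALSE))
  }
  out <- rows_of("multivariable", fit_linear(rows, predictors), adjusted = TRUE)
  for (pr in predictors) {
    out <- rbind(out, rows_of(pr, fit_linear(rows, pr), adjusted = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' @export
print.qus_fit <- function(x, ...) {
  cat(sprintf("<qus_fit> %s model (%s), predictors: %s\n", x$model_type,
              x$form, paste(x$predictors, collapse = " + ")))
  cat(sprintf("  n = %d, rss = %.4f, LL = %.2f, converged = %s\n",
              x$n, x$rss, x$loglik, x$converged))
  utils::str(x$coefficients, give.attr = FALSE)
  invisible(x)
}

#' @export
print.qus_lr <- function(x, ...) {
  cat(sprintf("LR statistic = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p))
  invisible(x)
}
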