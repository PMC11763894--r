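# Compound fat-fraction predictor: a linear multivariable model below, and a
# nonlinear (exponential) model at or above, a pair of (AC, BSC-D) switching
# thresholds found by grid search on the training set. Two variants:
#   CMT - nonlinear branch uses AC + BSC-D
#   CAC - nonlinear branch uses AC only

#' Assemble a compound (linear / nonlinear) model
#'
#' @param linear fitted linear model (`qus_fit`), the below-threshold branch.
#' @param nonlinear fitted exponential model (`qus_fit`), the branch used at
#'   or above the thresholds.
#' @param t_ac AC switching threshold, dB/cm/MHz.
#' @param t_bscd BSC-D switching threshold.
#' @param variant `"CMT"` (nonlinear multivariable) or `"CAC"`
#'   (nonlinear AC-only); descriptive label only.
#' @return object of class `qus_compound`.
#' @export
compound_model <- function(linear, nonlinear, t_ac, t_bscd,
                           variant = c("CMT", "CAC")) {
  variant <- match.arg(variant)
  stopifnot(inherits(linear, "qus_fit"), linear$model_type == "linear",
            inherits(nonlinear, "qus_fit"), nonlinear$model_type == "exp",
            is.numeric(t_ac), is.numeric(t_bscd))
  structure(list(linear = linear, nonlinear = nonlinear,
                 t_ac = t_ac, t_bscd = t_bscd, variant = variant),
            class = "qus_compound")
}

#' Predict fat fraction with a compound model
#'
#' A row is routed to the nonlinear branch iff `ac >= t_ac` AND
#' `bscd >= t_bscd` (both inclusive); otherwise the linear branch applies.
#' The per-row branch is attached as attribute `"branch"`
#' (`"linear"`/`"nonlinear"`) for audit.
#'
#' @param cm a `qus_compound`.
#' @param rows rows with `ac`, `bscd` and any other predictor columns the
#'   branch models need.
#' @return numeric vector of predicted fat fractions with a `branch`
#'   attribute.
#' @export
compound_predict <- function(cm, rows) {
  stopifnot(inherits(cm, "qus_compound"))
  rows <- as.data.frame(rows)
  missing_cols <- setdiff(c("ac", "bscd"), names(rows))
  if (length(missing_cols)) {
    stop("column(s) absent: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  nonlin <- rows$ac >= cm$t_ac & rows$bscd >= cm$t_bscd
  pred <- numeric(nrow(rows))
  if (any(!nonlin)) pred[!nonlin] <- predict(cm$linear, rows[!nonlin, , drop = FALSE])
  if (any(nonlin)) pred[nonlin] <- predict(cm$nonlinear, rows[nonlin, , drop = FALSE])
  attr(pred, "branch") <- ifelse(nonlin, "nonlinear", "linear")
  pred
}

#' Grid search over (AC, BSC-D) switching thresholds
#'
#' Scores every candidate threshold pair by forming compound predictions on
#' the training rows and computing R-squared (squared Pearson) and ICC(A,1)
#' against MRI-PDFF. Both full matrices are returned for heatmap export. The
#' selected pair maximizes R-squared; ties are broken by higher ICC, then by
#' the lexicographically lowest `(t_ac, t_bscd)`. Pairs routing all rows to
#' one branch are still scored (they reproduce the single-model fit); cells
#' where a metric is undefined are NA.
#'
#' @param rows training rows with `ac`, `bscd`, `pdff`.
#' @param linear,nonlinear fitted branch models (`qus_fit`).
#' @param ac_values,bscd_values ascending candidate thresholds. Defaults
#'   span 0.75-0.94 dB/cm/MHz in 0.01 steps and 89-108 in unit steps (a
#'   20 x 20 grid at measurement precision).
#' @return object of class `qus_grid`: `ac_values`, `bscd_values`,
#'   `r2_matrix`, `icc_matrix` (AC by BSC-D), `t_ac`, `t_bscd`, `best_r2`,
#'   `best_icc`.
#' @export
grid_search_thresholds <- function(rows, linear, nonlinear,
                                   ac_values = seq(0.75, 0.94, by = 0.01),
                                   bscd_values = seq(89, 108, by = 1)) {
  rows <- as.data.frame(rows)
  stopifnot(all(c("ac", "bscd", "pdff") %in% names(rows)),
            !is.unsorted(ac_values), !is.unsorted(bscd_values),
            length(ac_values) >= 1, length(bscd_values) >= 1)
  lin_pred <- predict(linear, rows)
  non_pred <- predict(nonlinear, rows)
  pdff <- rows$pdff
  na <- length(ac_values); nb <- length(bscd_values)
  r2m <- matrix(NA_real_, na, nb, dimnames = list(ac_values, bscd_values))
  iccm <- r2m
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      sel <- rows$ac >= ac_values[i] & rows$bscd >= bscd_values[j]
      pred <- ifelse(sel, non_pred, lin_pred)
      if (stats::sd(pred) > 0) {
        r2m[i, j] <- stats::cor(pred, pdff)^2
        iccm[i, j] <- icc_a1(pred, pdff)
      }
    }
  }
  # best cell: max R2, tie -> max ICC, tie -> lowest (t_ac, t_bscd)
  best <- c(1L, 1L); best_score <- c(-Inf, -Inf)
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      score <- c(r2m[i, j], iccm[i, j])
      if (any(is.na(score))) next
      if (score[1] > best_score[1] ||
          (score[1] == best_score[1] && score[2] > best_score[2])) {
        best <- c(i, j); best_score <- score
      }
    }
  }
  structure(list(ac_values = ac_values, bscd_values = bscd_values,
                 r2_matrix = r2m, icc_matrix = iccm,
                 t_ac = ac_values[best[1]], t_bscd = bscd_values[best[2]],
                 best_r2 = best_score[1], best_icc = best_score[2]),
            class = "qus_grid")
}

#' @export
print.qus_grid <- function(x, ...) {
  cat(sprintf("<qus_grid> %d x %d thresholds; best t_ac = %g, t_bscd = %g (R2 = %.3f, ICC = %.3f)\n",
              length(x$ac_values), length(x$bscd_values),
              x$t_ac, x$t_bscd, x$best_r2, x$best_icc))
  invisible(x)
}

#' Export grid-search matrices as heatmap CSVs
#'
#' One CSV per metric: rows are AC thresholds, columns BSC-D thresholds.
#'
#' @param grid a `qus_grid`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return paths of the two files, invisibly.
#' @export
write_grid <- function(grid, dir, prefix = "grid") {
  stopifnot(inherits(grid, "qus_grid"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, "_", c("r2", "icc"), ".csv"))
  for (k in 1:2) {
    m <- if (k == 1) grid$r2_matrix else grid$icc_matrix
    df <- data.frame(t_ac = grid$ac_values, m, check.names = FALSE)
    utils::write.csv(df, paths[k], row.names = FALSE)
  }
  invisible(paths)
}

#' Build a compound model from training data
#'
#' Fits the linear multivariable (AC + BSC-D) branch and the variant's
#' nonlinear branch (CMT: AC + BSC-D; CAC: AC only) — optionally under
#' repeated k-fold cross-validation for performance reporting — then runs
#' the threshold grid search and assembles the compound model. Both branch
#' models are fitted on the full training set; the thresholds only decide
#' which model predicts each subject.
#'
#' @param rows training rows with `ac`, `bscd`, `pdff`.
#' @param variant `"CMT"` or `"CAC"`.
#' @param cv a [cv_spec()], or NULL to skip cross-validation.
#' @param ac_values,bscd_values threshold candidates, see
#'   [grid_search_thresholds()].
#' @return list of class `qus_compound_build`: `compound` (`qus_compound`),
#'   `grid` (`qus_grid`), `linear`, `nonlinear` (branch fits), `cv_linear`,
#'   `cv_nonlinear` (CV reports or NULL), and `training` with the pooled
#'   compound residual statistics (`rss`, `loglik`, `n_params` = sum of both
#'   branches' parameter counts, `r_squared`, `icc`) for likelihood-ratio
#'   style comparison against the single models.
#' @export
build_compound <- function(rows, variant = c("CMT", "CAC"), cv = cv_spec(),
                           ac_values = seq(0.75, 0.94, by = 0.01),
                           bscd_values = seq(89, 108, by = 1)) {
  variant <- match.arg(variant)
  rows <- as.data.frame(rows)
  nonlin_predictors <- if (variant == "CMT") c("ac", "bscd") else "ac"
  if (is.null(cv)) {
    cv_linear <- cv_nonlinear <- NULL
    linear <- fit_linear(rows, c("ac", "bscd"))
    nonlinear <- fit_exp(rows, nonlin_predictors)
  } else {
    cv_linear <- repeated_kfold_train(rows, "linear", c("ac", "bscd"), cv)
    cv_nonlinear <- repeated_kfold_train(rows, "exp", nonlin_predictors, cv)
    linear <- cv_linear$fit
    nonlinear <- cv_nonlinear$fit
  }
  grid <- grid_search_thresholds(rows, linear, nonlinear, ac_values, bscd_values)
  cm <- compound_model(linear, nonlinear, grid$t_ac, grid$t_bscd, variant)
  pred <- compound_predict(cm, rows)
  rss <- sum((pred - rows$pdff)^2)
  structure(
    list(compound = cm, grid = grid, linear = linear, nonlinear = nonlinear,
         cv_linear = cv_linear, cv_nonlinear = cv_nonlinear,
         training = list(
           n = nrow(rows), rss = rss,
           loglik = gaussian_loglik(rss, nrow(rows)),
           n_params = linear$n_params + nonlinear$n_params,
           r_squared = stats::cor(pred, rows$pdff)^2,
           icc = icc_a1(pred, rows$pdff))),
    class = "qus_compound_build")
}

#' @export
print.qus_compound <- function(x, ...) {
  cat(sprintf("<qus_compound> %s: linear below, nonlinear at ac >= %g & bscd >= %g\n",
              x$variant, x$t_ac, x$t_bscd))
  invisible(x)
}

#' @export
print.qus_compound_build <- function(x, ...) {
  print(x$compound)
  cat(sprintf("  training: R2 = %.3f, ICC = %.3f, LL = %.2f (n = %d)\n",
              x$training$r_squared, x$training$icc, x$training$loglik,
              x$training$n))
  invisible(x)
}
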