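# Agreement and correlation statistics for predicted fat fractions against
# the MRI-PDFF reference, plus the repeated k-fold cross-validation protocol
# used for model training and comparison.

#' Cross-validation specification
#'
#' @param folds number of folds (default 3).
#' @param repeats number of repeats (default 5).
#' @param seed integer seed controlling the fold partitions.
#' @return list of class `qus_cv`.
#' @export
cv_spec <- function(folds = 3L, repeats = 5L, seed = 1L) {
  stopifnot(folds >= 2, repeats >= 1)
  structure(list(folds = as.integer(folds), repeats = as.integer(repeats),
                 seed = as.integer(seed)),
            class = "qus_cv")
}

#' Pearson correlation between predictions and reference
#'
#' Sample Pearson r with the p-value from the t transform on n - 2 degrees
#' of freedom (via [stats::cor.test()]).
#'
#' @param pred,ref numeric vectors of equal length, n >= 3.
#' @return list: `r`, `r_squared`, `p`, `n`.
#' @export
pearson_eval <- function(pred, ref) {
  stopifnot(length(pred) == length(ref))
  keep <- stats::complete.cases(pred, ref)
  pred <- pred[keep]; ref <- ref[keep]
  if (length(pred) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(pred) == 0 || stats::sd(ref) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(pred, ref)
  r <- unname(ct$estimate)
  list(r = r, r_squared = r^2, p = ct$p.value, n = length(pred))
}

#' Intraclass correlation, two-way model, absolute agreement, single measure
#'
#' ICC(A,1) between a prediction and the MRI-PDFF reference, treating the
#' two methods as the k = 2 columns of a subjects-by-methods two-way layout:
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n) (MSC - MSE))`, with MSR,
#' MSC, MSE the row (subject), column (method) and residual mean squares.
#' Unlike Pearson r, a constant bias between the methods lowers the ICC.
#'
#' @param pred,ref numeric vectors of equal length, n >= 3.
#' @return single ICC value in \[-1, 1\].
#' @export
icc_a1 <- function(pred, ref) {
  stopifnot(length(pred) == length(ref))
  keep <- stats::complete.cases(pred, ref)
  Y <- cbind(pred[keep], ref[keep])
  n <- nrow(Y)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (all(Y == Y[1, 1])) stop("degenerate data: all values equal", call. = FALSE)
  k <- 2
  grand <- mean(Y)
  row_means <- rowMeans(Y)
  col_means <- colMeans(Y)
  msr <- k * sum((row_means - grand)^2) / (n - 1)
  msc <- n * sum((col_means - grand)^2) / (k - 1)
  sse <- sum((Y - outer(row_means, rep(1, k)) -
                outer(rep(1, n), col_means) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

#' Bland-Altman agreement between two fat-fraction measurements
#'
#' Mean bias `mean(a - b)` and limits of agreement `bias +/- 1.96 * sd(a - b)`
#' (sample SD, n - 1 denominator). The paired means and differences are
#' returned for plotting.
#'
#' @param a,b numeric vectors of equal length, n >= 2.
#' @return list of class `qus_ba`: `bias`, `loa_low`, `loa_high`, `sd_diff`,
#'   `means`, `diffs`, `n`.
#' @export
bland_altman <- function(a, b) {
  stopifnot(length(a) == length(b))
  keep <- stats::complete.cases(a, b)
  a <- a[keep]; b <- b[keep]
  if (length(a) < 2) stop("need at least 2 complete pairs", call. = FALSE)
  d <- a - b
  bias <- mean(d)
  sd_d <- stats::sd(d)
  structure(list(bias = bias, loa_low = bias - 1.96 * sd_d,
                 loa_high = bias + 1.96 * sd_d, sd_diff = sd_d,
                 means = (a + b) / 2, diffs = d, n = length(a)),
            class = "qus_ba")
}

#' @export
print.qus_ba <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias = %.3f%%, LOA = [%.3f%%, %.3f%%], n = %d\n",
              x$bias, x$loa_low, x$loa_high, x$n))
  invisible(x)
}

#' Grade-stratified evaluation of predictions
#'
#' Partitions rows by the MRI-PDFF-derived steatosis grade (the reference
#' standard, never the predicted grade) and reports Pearson and ICC(A,1) per
#' group. Groups with fewer than 3 subjects are flagged not-evaluable
#' instead of raising.
#'
#' @param pred predicted fat fractions, one per row of `rows`.
#' @param rows cohort rows with a `pdff` column.
#' @param grouping `"all"` (single group), `"low_high"` (S0+S1 vs S2+S3),
#'   or `"per_grade"`.
#' @return data.frame: `subgroup`, `n`, `evaluable`, `pearson_r`,
#'   `r_squared`, `pearson_p`, `icc`.
#' @export
evaluate_by_grade <- function(pred, rows, grouping = c("all", "low_high", "per_grade")) {
  grouping <- match.arg(grouping)
  rows <- as.data.frame(rows)
  stopifnot(length(pred) == nrow(rows), "pdff" %in% names(rows))
  grade <- classify_steatosis(rows$pdff)
  groups <- switch(grouping,
    all = list(all = rep(TRUE, nrow(rows))),
    low_high = list("S0+S1" = grade %in% c("S0", "S1"),
                    "S2+S3" = grade %in% c("S2", "S3")),
    per_grade = stats::setNames(
      lapply(levels(grade), function(g) grade == g), levels(grade)))
  out <- lapply(names(groups), function(label) {
    mask <- groups[[label]]
    n <- sum(mask)
    if (n < 3 || stats::sd(rows$pdff[mask]) == 0 || stats::sd(pred[mask]) == 0) {
      return(data.frame(subgroup = label, n = n, evaluable = FALSE,
                        pearson_r = NA_real_, r_squared = NA_real_,
                        pearson_p = NA_real_, icc = NA_real_))
    }
    pe <- pearson_eval(pred[mask], rows$pdff[mask])
    data.frame(subgroup = label, n = n, evaluable = TRUE, pearson_r = pe$r,
               r_squared = pe$r_squared, pearson_p = pe$p,
               icc = icc_a1(pred[mask], rows$pdff[mask]))
  })
  do.call(rbind, out)
}

#' Bonferroni significance decisions
#'
#' Compares each raw p-value against `alpha / m`, `m` the number of
#' comparisons in the family.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param m family size; defaults to `length(p)`.
#' @param alpha family-wise error rate (default 0.05).
#' @return data.frame: `p`, `threshold`, `significant`.
#' @export
bonferroni_adjust <- function(p, m = length(p), alpha = 0.05) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE), m >= 1)
  data.frame(p = p, threshold = alpha / m, significant = p < alpha / m)
}

# Even fold sizes (remainder to the first folds) assigned to shuffled row
# indices; returns integer fold id per row.
fold_assignment <- function(n, folds) {
  sizes <- rep(n %/% folds, folds)
  rem <- n %% folds
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  ids <- rep(seq_len(folds), times = sizes)
  ids[sample.int(n)]
}

#' Repeated k-fold cross-validated training
#'
#' For each repeat, rows are partitioned at random (seeded) into `folds`
#' folds; the model is fitted on each training complement and scored on the
#' held-out fold (Pearson r, R-squared, ICC(A,1)). The returned model is a
#' refit on the full data — cross-validation is used for performance
#' estimation and model comparison only. Identical `(data, cv)` inputs give
#' bit-identical partitions and metrics.
#'
#' @param rows training rows with `pdff` and predictor columns.
#' @param form `"linear"` or `"exp"`.
#' @param predictors predictor set, see [fit_linear()].
#' @param cv a [cv_spec()].
#' @return list of class `qus_cvfit`: `fit` (full-data refit), `cv`
#'   (data.frame with one row per repeat x fold), `cv_summary` (means over
#'   folds), `cv_spec`, and `rng_algorithm` recording the fold-shuffling
#'   generator for reproducibility.
#' @export
repeated_kfold_train <- function(rows, form = c("linear", "exp"), predictors,
                                 cv = cv_spec()) {
  form <- match.arg(form)
  stopifnot(inherits(cv, "qus_cv"))
  df <- model_frame(as.data.frame(rows), check_predictors(predictors))
  n <- nrow(df)
  if (n < cv$folds) stop("fewer rows than folds", call. = FALSE)
  fitter <- if (form == "linear") fit_linear else fit_exp
  min_rows <- length(predictors) + if (form == "linear") 3L else 4L

  records <- list()
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  for (rep_i in seq_len(cv$repeats)) {
    set.seed((cv$seed %% 2147483L) * 1000L + rep_i)
    ids <- fold_assignment(n, cv$folds)
    for (try in seq_len(100)) {
      complements_ok <- all(vapply(seq_len(cv$folds),
                                   function(f) sum(ids != f) >= min_rows,
                                   logical(1)))
      if (complements_ok) break
      ids <- fold_assignment(n, cv$folds)
    }
    if (!complements_ok) stop("could not build valid folds", call. = FALSE)
    for (fold in seq_len(cv$folds)) {
      hold <- ids == fold
      fit_f <- fitter(df[!hold, , drop = FALSE], predictors)
      pred <- predict(fit_f, df[hold, , drop = FALSE])
      obs <- df$pdff[hold]
      evaluable <- sum(hold) >= 3 && stats::sd(obs) > 0 && stats::sd(pred) > 0
      records[[length(records) + 1L]] <- data.frame(
        rep = rep_i, fold = fold, n_test = sum(hold),
        r = if (evaluable) pearson_eval(pred, obs)$r else NA_real_,
        r_squared = if (evaluable) pearson_eval(pred, obs)$r_squared else NA_real_,
        icc = if (evaluable) icc_a1(pred, obs) else NA_real_,
        rmse = sqrt(mean((pred - obs)^2)))
    }
  }
  cv_df <- do.call(rbind, records)
  structure(
    list(fit = fitter(df, predictors),
         cv = cv_df,
         cv_summary = colMeans(cv_df[c("r", "r_squared", "icc", "rmse")],
                               na.rm = TRUE),
         cv_spec = cv,
         rng_algorithm = RNGkind()[1]),
    class = "qus_cvfit")
}

#' @export
print.qus_cvfit <- function(x, ...) {
  cat(sprintf("<qus_cvfit> %d-fold x %d repeats (seed %d, %s)\n",
              x$cv_spec$folds, x$cv_spec$repeats, x$cv_spec$seed,
              x$rng_algorithm))
  cat(sprintf("  CV means: r = %.3f, R2 = %.3f, ICC = %.3f, RMSE = %.3f\n",
              x$cv_summary["r"], x$cv_summary["r_squared"],
              x$cv_summary["icc"], x$cv_summary["rmse"]))
  print(x$fit)
  invisible(x)
}
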