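# Cohort container: a plain data.frame with class "qus_cohort", one row per
# subject, fixed column order. Mandatory: subject_id, split, ac, bscd, pdff.
# Optional: usff, bmi, sld, ls, age, sex (NA when absent).

cohort_columns <- c("subject_id", "split", "ac", "bscd", "pdff",
                    "usff", "bmi", "sld", "ls", "age", "sex")
cohort_mandatory <- c("subject_id", "split", "ac", "bscd", "pdff")

#' Assemble a validated QUS cohort table
#'
#' @param df data.frame holding at least `subject_id`, `split`, `ac`,
#'   `bscd`, `pdff`; optional columns `usff`, `bmi`, `sld`, `ls`, `age`,
#'   `sex` are carried along, extra columns are dropped.
#' @param provenance free-text origin (file path or generator settings).
#' @return a `qus_cohort` data.frame with the fixed column order.
#' @details Row-level invariants: `ac > 0`, `bscd > 0`, `pdff` in \[0, 100\],
#'   `usff` (if present) in \[0, 100\], `ls` (if present) `> 0`, `split` one
#'   of train/test, unique `subject_id`. Violating rows raise an error that
#'   lists the offending row indices.
#' @export
as_cohort <- function(df, provenance = "in-memory") {
  missing_cols <- setdiff(cohort_mandatory, names(df))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (col in setdiff(cohort_columns, names(df))) df[[col]] <- rep(NA, nrow(df))
  df <- df[cohort_columns]
  num_cols <- c("ac", "bscd", "pdff", "usff", "bmi", "sld", "ls", "age")
  for (col in num_cols) df[[col]] <- as.numeric(df[[col]])
  df$subject_id <- as.character(df$subject_id)
  df$split <- as.character(df$split)
  df$sex <- as.character(df$sex)

  problems <- cohort_row_problems(df)
  if (length(problems)) {
    stop("invalid cohort rows:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  if (anyDuplicated(df$subject_id)) {
    stop("duplicate subject_id: ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]), collapse = ", "),
         call. = FALSE)
  }
  rownames(df) <- NULL
  structure(df, class = c("qus_cohort", "data.frame"), provenance = provenance)
}

# character vector of row-indexed diagnostics, empty when all rows valid
cohort_row_problems <- function(df) {
  checks <- list(
    "ac must be > 0"          = !is.na(df$ac) & df$ac > 0,
    "bscd must be > 0"        = !is.na(df$bscd) & df$bscd > 0,
    "pdff must be in [0,100]" = !is.na(df$pdff) & df$pdff >= 0 & df$pdff <= 100,
    "usff must be in [0,100]" = is.na(df$usff) | (df$usff >= 0 & df$usff <= 100),
    "ls must be > 0"          = is.na(df$ls) | df$ls > 0,
    "split must be train/test" = !is.na(df$split) & df$split %in% c("train", "test"),
    "sex must be female/male" = is.na(df$sex) | df$sex %in% c("female", "male")
  )
  problems <- character(0)
  for (msg in names(checks)) {
    bad <- which(!checks[[msg]])
    if (length(bad)) {
      problems <- c(problems, sprintf("row %d: %s", bad, msg))
    }
  }
  problems
}

#' Read a cohort CSV
#'
#' Expects the standard header (`subject_id, split, ac, bscd, pdff, usff,
#' bmi, sld, ls, age, sex`); extra columns are ignored, missing optional
#' columns become NA. Rows violating the subject invariants abort with
#' row-indexed diagnostics.
#'
#' @param path CSV file path.
#' @return a `qus_cohort`.
#' @seealso [write_cohort()]
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(cohort_mandatory, names(df))
  if (length(missing_cols)) {
    stop("missing mandatory column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  num_cols <- intersect(c("ac", "bscd", "pdff", "usff", "bmi", "sld", "ls", "age"),
                        names(df))
  for (col in num_cols) {
    raw <- df[[col]]
    val <- suppressWarnings(as.numeric(raw))
    unparseable <- which(!is.na(raw) & raw != "" & is.na(val))
    if (length(unparseable)) {
      stop("unparseable numeric in column '", col, "', row(s): ",
           paste(unparseable, collapse = ", "), call. = FALSE)
    }
    df[[col]] <- val
  }
  if (!is.null(df$sex)) df$sex[!is.na(df$sex) & df$sex == ""] <- NA
  as_cohort(df, provenance = path)
}

#' Write a cohort CSV
#'
#' Fixed column order, comma-delimited, dot decimal separator, full numeric
#' precision (up to 17 significant digits); missing optional values are empty
#' cells. `write_cohort()` then `read_cohort()` is lossless for values with a
#' finite decimal representation.
#'
#' @param cohort a `qus_cohort`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "qus_cohort"))
  out <- as.data.frame(cohort)[cohort_columns]
  for (col in names(out)) {
    if (is.numeric(out[[col]])) {
      txt <- vapply(out[[col]], function(x) {
        if (is.na(x)) "" else format(x, digits = 17, scientific = FALSE, trim = TRUE)
      }, character(1))
      out[[col]] <- txt
    } else {
      out[[col]][is.na(out[[col]])] <- ""
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @export
print.qus_cohort <- function(x, ...) {
  cat(sprintf("<qus_cohort> %d subjects (%s)\n", nrow(x),
              paste(sprintf("%s: %d", names(table(x$split)), table(x$split)),
                    collapse = ", ")))
  cat("provenance:", attr(x, "provenance"), "\n")
  NextMethod()
}

#' Restrict a cohort to one split
#'
#' @param cohort a `qus_cohort`.
#' @param split `"train"` or `"test"`.
#' @return the matching rows, still a `qus_cohort`.
#' @export
cohort_split <- function(cohort, split) {
  stopifnot(split %in% c("train", "test"))
  out <- cohort[cohort$split == split, , drop = FALSE]
  rownames(out) <- NULL
  out
}
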