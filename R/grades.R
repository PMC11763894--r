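#' Grade hepatic steatosis from MRI-PDFF
#'
#' Maps a proton-density fat fraction (percent) to the four-level steatosis
#' grade using the fixed cut-offs 5%, 15% and 20%. Intervals are lower-closed:
#' a value exactly at a cut-off belongs to the higher grade, matching the
#' convention that >= 5% liver fat defines steatosis.
#'
#' @param pdff numeric vector of MRI-PDFF values in percent, in \[0, 100\].
#' @return factor with levels `S0 < S1 < S2 < S3`.
#' @examples
#' classify_steatosis(c(0, 4.9, 5, 16.5, 20))
#' @export
classify_steatosis <- function(pdff) {
  if (!is.numeric(pdff)) stop("`pdff` must be numeric", call. = FALSE)
  bad <- !is.na(pdff) & (pdff < 0 | pdff > 100)
  if (any(bad)) {
    stop("`pdff` out of [0, 100] at position(s): ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  cut(pdff, breaks = c(-Inf, 5, 15, 20, Inf), right = FALSE,
      labels = c("S0", "S1", "S2", "S3"), ordered_result = TRUE)
}

#' Grade liver fibrosis from shear-wave stiffness
#'
#' Maps 2D shear-wave elastography liver stiffness (kPa) to the "rule of 4"
#' fibrosis grades with cut-offs 5, 9 and 13 kPa; intervals are lower-closed.
#'
#' @param ls numeric vector of liver stiffness in kPa, strictly positive.
#' @return factor with levels `F0/1 < F2 < F3 < F4`.
#' @examples
#' classify_fibrosis(c(4.99, 7.59, 13))
#' @export
classify_fibrosis <- function(ls) {
  if (!is.numeric(ls)) stop("`ls` must be numeric", call. = FALSE)
  bad <- !is.na(ls) & ls <= 0
  if (any(bad)) {
    stop("`ls` must be positive; offending position(s): ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  cut(ls, breaks = c(-Inf, 5, 9, 13, Inf), right = FALSE,
      labels = c("F0/1", "F2", "F3", "F4"), ordered_result = TRUE)
}
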