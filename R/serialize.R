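# Flat key=value text serialization for fitted models, so trained models can
# be reused by the compound builder and the command-line tools. Numbers are
# written with 17 significant digits (round-trip exact for doubles).

fmt_num <- function(x) sprintf("%.17g", x)

fit_to_lines <- function(fit, prefix = "") {
  cf <- fit$coefficients
  lines <- c(
    paste0(prefix, "model_type=", fit$model_type),
    paste0(prefix, "form=", fit$form),
    paste0(prefix, "predictors=", paste(fit$predictors, collapse = ",")),
    paste0(prefix, "n=", fit$n),
    paste0(prefix, "rss=", fmt_num(fit$rss)),
    paste0(prefix, "n_params=", fit$n_params),
    paste0(prefix, "converged=", fit$converged))
  if (fit$model_type == "linear") {
    lines <- c(lines,
               paste0(prefix, "beta.", fit$predictors, "=", fmt_num(cf$betas)),
               paste0(prefix, "intercept=", fmt_num(cf$intercept)))
  } else {
    amp <- cf$amplitude
    amp_lines <- if (length(amp) == 1) {
      paste0(prefix, "amplitude=", fmt_num(amp))
    } else {
      paste0(prefix, "amplitude.", names(amp), "=", fmt_num(amp))
    }
    lines <- c(lines, amp_lines,
               paste0(prefix, "rate.", fit$predictors, "=", fmt_num(cf$rates)),
               paste0(prefix, "offset=", fmt_num(cf$offset)))
  }
  lines
}

lines_to_fit <- function(kv) {
  predictors <- strsplit(kv[["predictors"]], ",")[[1]]
  model_type <- kv[["model_type"]]
  num <- function(key) as.numeric(kv[[key]])
  if (model_type == "linear") {
    coefficients <- list(
      betas = vapply(paste0("beta.", predictors), num, numeric(1), USE.NAMES = FALSE),
      intercept = num("intercept"))
  } else {
    amp <- if ("amplitude" %in% names(kv)) num("amplitude") else
      stats::setNames(vapply(paste0("amplitude.", predictors), num, numeric(1),
                             USE.NAMES = FALSE), predictors)
    coefficients <- list(
      amplitude = amp,
      rates = stats::setNames(vapply(paste0("rate.", predictors), num,
                                     numeric(1), USE.NAMES = FALSE), predictors),
      offset = num("offset"))
  }
  new_qus_fit(model_type = model_type, form = kv[["form"]],
              predictors = predictors, coefficients = coefficients,
              n = as.integer(kv[["n"]]), rss = num("rss"),
              n_params = as.integer(kv[["n_params"]]),
              converged = as.logical(kv[["converged"]]))
}

#' Serialize a fitted model to a flat key-value text file
#'
#' Works for single fits ([fit_linear()], [fit_exp()]) and compound models
#' ([compound_model()]), whose two branch models are embedded under
#' `linear.` / `nonlinear.` key prefixes. Coefficients are stored at full
#' double precision.
#'
#' @param model a `qus_fit` or `qus_compound`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  if (inherits(model, "qus_fit")) {
    lines <- fit_to_lines(model)
  } else if (inherits(model, "qus_compound")) {
    lines <- c(
      "model_type=compound",
      paste0("variant=", model$variant),
      paste0("t_ac=", fmt_num(model$t_ac)),
      paste0("t_bscd=", fmt_num(model$t_bscd)),
      fit_to_lines(model$linear, prefix = "linear."),
      fit_to_lines(model$nonlinear, prefix = "nonlinear."))
  } else {
    stop("cannot serialize objects of class ", paste(class(model), collapse = "/"),
         call. = FALSE)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a model written by [write_model()]
#'
#' @param path key-value model file.
#' @return a `qus_fit` or `qus_compound`.
#' @export
read_model <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  keys <- sub("=.*$", "", lines)
  vals <- sub("^[^=]*=", "", lines)
  kv <- stats::setNames(as.list(vals), keys)
  if (kv[["model_type"]] == "compound") {
    pick <- function(prefix) {
      sel <- startsWith(keys, prefix)
      stats::setNames(as.list(vals[sel]), substring(keys[sel], nchar(prefix) + 1))
    }
    compound_model(
      linear = lines_to_fit(pick("linear.")),
      nonlinear = lines_to_fit(pick("nonlinear.")),
      t_ac = as.numeric(kv[["t_ac"]]), t_bscd = as.numeric(kv[["t_bscd"]]),
      variant = kv[["variant"]])
  } else {
    lines_to_fit(kv)
  }
}
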