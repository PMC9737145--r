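#' Coefficient of determination
#'
#' `R2 = 1 - SSE/SST`, with SST about the mean of the reference values.
#'
#' @param y_true reference values.
#' @param y_pred predictions, same length.
#' @return Scalar R-squared (can be negative for a model worse than the mean).
#' @export
r_squared <- function(y_true, y_pred) {
  check_paired(y_true, y_pred)
  sst <- sum((y_true - mean(y_true))^2)
  if (sst == 0) stop("reference values are constant: R2 is undefined")
  1 - sum((y_true - y_pred)^2) / sst
}

#' Root mean square error
#'
#' @inheritParams r_squared
#' @return Scalar RMSE, >= 0.
#' @export
rmse <- function(y_true, y_pred) {
  check_paired(y_true, y_pred)
  sqrt(mean((y_true - y_pred)^2))
}

#' Ratio of performance to deviation
#'
#' `RPD = sd(reference) / RMSEP` on the validation set, using the population
#' standard deviation. Conventional reading: below 1.4 unreliable, 1.4-2
#' fairly reliable, above 2 suitable for quantification.
#'
#' @inheritParams r_squared
#' @return Scalar RPD; `Inf` with a warning when RMSEP is zero.
#' @export
rpd <- function(y_true, y_pred) {
  check_paired(y_true, y_pred)
  sd_pop <- sqrt(mean((y_true - mean(y_true))^2))
  if (sd_pop == 0) stop("reference values are constant: RPD is undefined")
  e <- rmse(y_true, y_pred)
  if (e == 0) {
    warning("zero RMSEP: RPD is infinite")
    return(Inf)
  }
  sd_pop / e
}

#' Qualitative RPD band
#'
#' @param x an RPD value.
#' @return `"unreliable"` (< 1.4), `"fairly reliable"` (1.4-2), or
#'   `"quantification-grade"` (> 2).
#' @export
rpd_band <- function(x) {
  if (x < 1.4) "unreliable"
  else if (x <= 2) "fairly reliable"
  else "quantification-grade"
}

check_paired <- function(y_true, y_pred) {
  if (length(y_true) == 0 || length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal, nonzero length")
  invisible(NULL)
}

#' Evaluate a fitted model on a calibration/validation split
#'
#' Computes the standard chemometric report: Rc2 and RMSEC on the
#' calibration set, Rv2, RMSEP and RPD on the validation set, plus the
#' reference range of the target over all samples.
#'
#' @param bundle a fitted `model_bundle`.
#' @param split a `split_spec` from [split_samples()].
#' @param X preprocessed [spectrum_matrix()] covering both sets.
#' @param y named target vector aligned with `X`'s sample ids.
#' @return A one-row `data.frame` of class `evaluation_report` with columns
#'   `target`, `method`, `range_min`, `range_max`, `Rc2`, `RMSEC`, `Rv2`,
#'   `RMSEP`, `RPD`, `RPD_band`, `n_cal`, `n_val`.
#' @export
evaluate_model <- function(bundle, split, X, y) {
  stopifnot_spectrum_matrix(X)
  ids <- X$sample_ids
  unknown <- setdiff(c(split$calibration, split$validation), ids)
  if (length(unknown))
    stop("split refers to unknown sample ids: ", paste(unknown, collapse = ", "))
  if (is.null(names(y))) names(y) <- ids
  Xc <- sm_subset(X, split$calibration)
  Xv <- sm_subset(X, split$validation)
  yc <- y[split$calibration]
  yv <- y[split$validation]
  pc <- predict(bundle, Xc)
  pv <- predict(bundle, Xv)
  rpd_v <- rpd(yv, pv)
  out <- data.frame(
    target = bundle$target,
    method = if (length(bundle$provenance)) paste(bundle$provenance, collapse = "+") else "raw",
    range_min = min(y), range_max = max(y),
    Rc2 = r_squared(yc, pc), RMSEC = rmse(yc, pc),
    Rv2 = r_squared(yv, pv), RMSEP = rmse(yv, pv),
    RPD = rpd_v, RPD_band = rpd_band(rpd_v),
    n_cal = length(yc), n_val = length(yv))
  class(out) <- c("evaluation_report", "data.frame")
  out
}

#' Measured-versus-predicted scatter data
#'
#' The data behind a measured/predicted diagnostic plot: one row per sample
#' with its reference value, prediction, and set label.
#'
#' @inheritParams evaluate_model
#' @return `data.frame` with columns `sample_id`, `set`
#'   (`"calibration"`/`"validation"`), `measured`, `predicted`.
#' @export
prediction_scatter <- function(bundle, split, X, y) {
  stopifnot_spectrum_matrix(X)
  if (is.null(names(y))) names(y) <- X$sample_ids
  rows <- lapply(c(calibration = "calibration", validation = "validation"),
                 function(set) {
    ids <- split[[set]]
    data.frame(sample_id = ids, set = set, measured = unname(y[ids]),
               predicted = predict(bundle, sm_subset(X, ids)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read an evaluation report table
#'
#' Serializes one or more evaluation reports to the conventional group-range-
#' method CSV layout (`Group, Range, Method, Rc2, RMSEC, Rv2, RMSEP, RPD`)
#' and reads it back losslessly.
#'
#' @param reports an `evaluation_report` or a data.frame of row-bound reports.
#' @param path CSV path.
#' @return `path` (write) / the report data.frame (read).
#' @export
write_report_csv <- function(reports, path) {
  df <- data.frame(Group = reports$target,
                   Range = sprintf("%.2f-%.2f", reports$range_min, reports$range_max),
                   Method = reports$method,
                   Rc2 = reports$Rc2, RMSEC = reports$RMSEC,
                   Rv2 = reports$Rv2, RMSEP = reports$RMSEP, RPD = reports$RPD,
                   n_cal = reports$n_cal, n_val = reports$n_val)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_report_csv
#' @export
read_report_csv <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}
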