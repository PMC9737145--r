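# ranger requires named covariates; name matrix columns positionally so that
# training and prediction matrices of equal width always align.
rx <- function(x) {
  colnames(x) <- paste0("V", seq_len(ncol(x)))
  x
}

#' Random calibration/validation split
#'
#' Partitions samples into a calibration and a validation set at the given
#' ratio (default 3:2) by uniform random assignment.
#'
#' @param sample_ids vector of sample identifiers.
#' @param ratio length-2 numeric, calibration:validation (default `c(3, 2)`).
#' @param seed integer seed.
#' @return An object of class `split_spec` with `calibration` and
#'   `validation` id vectors.
#' @export
split_samples <- function(sample_ids, ratio = c(3, 2), seed = 1L) {
  n <- length(sample_ids)
  if (n < 5) stop("need at least 5 samples to honour the split ratio")
  frac <- ratio[1] / sum(ratio)
  n_cal <- round(frac * n)
  if (n_cal < 1 || n_cal >= n) stop("split ratio leaves an empty set")
  set.seed(seed)
  cal <- sort(sample.int(n, n_cal))
  structure(list(calibration = sample_ids[cal],
                 validation = sample_ids[-cal],
                 ratio = ratio, seed = seed),
            class = "split_spec")
}

#' Monte-Carlo cross-validation outlier screening
#'
#' Repeatedly fits a small random forest on a random subsample (default 80%)
#' and records absolute prediction residuals on the held-out remainder. Each
#' sample's mean held-out residual is converted to a robust outlyingness
#' score — its excess over the median in MAD units — and samples whose score
#' exceeds `threshold` are flagged as anomalous: their spectra do not
#' predict their labels the way the bulk of samples do.
#'
#' `y` may also be a matrix with one column per target (e.g. all chemical
#' group totals). Each cycle then screens every target on the same
#' subsample, and a sample's score is its worst (maximum) per-target score —
#' an apple whose spectrum contradicts any of its labels is suspect.
#'
#' The default `threshold = 6` looks generous against a normal reference,
#' but absolute held-out residuals are strongly right-skewed (forest
#' predictions compress towards the mean, so samples near the concentration
#' range edges carry large residuals even when clean) and the max over
#' targets pushes the clean tail further out; 6 MAD units above the median
#' sits beyond the 99th percentile of clean samples while genuine label
#' anomalies score far higher.
#'
#' @param X a [spectrum_matrix()].
#' @param y numeric target vector aligned with `X`, or a samples x targets
#'   matrix.
#' @param n_cycles number of subsampling cycles (study setting: 1000).
#' @param fraction subsample fraction (study setting: 0.8).
#' @param seed integer seed.
#' @param n_trees trees per screening forest (small by design; screening
#'   needs a stable residual ranking, not a tuned model).
#' @param threshold flagging cutoff on the MAD-standardized residual score.
#' @return An object of class `mccv_result`: per-sample inclusion counts,
#'   mean held-out absolute residuals, outlier flags, and the settings used.
#' @export
mccv_screen <- function(X, y, n_cycles = 1000L, fraction = 0.8, seed = 1L,
                        n_trees = 50L, threshold = 6) {
  stopifnot_spectrum_matrix(X)
  if (n_cycles < 1) stop("n_cycles must be at least 1")
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  n <- nrow(X$values)
  Y <- if (is.matrix(y)) y else matrix(y, ncol = 1)
  if (nrow(Y) != n) stop("target length does not match sample count")
  n_tgt <- ncol(Y)
  m <- round(fraction * n)
  included <- integer(n)
  res_sum <- matrix(0, n, n_tgt)
  res_cnt <- integer(n)
  set.seed(seed)
  cycle_seeds <- sample.int(.Machine$integer.max, n_cycles)
  for (cyc in seq_len(n_cycles)) {
    set.seed(cycle_seeds[cyc])
    tr <- sample.int(n, m)
    ho <- setdiff(seq_len(n), tr)
    xtr <- rx(X$values[tr, , drop = FALSE])
    xho <- rx(X$values[ho, , drop = FALSE])
    for (t in seq_len(n_tgt)) {
      fit <- ranger::ranger(x = xtr, y = Y[tr, t],
                            num.trees = n_trees, seed = cycle_seeds[cyc] + t,
                            num.threads = 1)
      pred <- stats::predict(fit, xho, num.threads = 1)$predictions
      res_sum[ho, t] <- res_sum[ho, t] + abs(pred - Y[ho, t])
    }
    included[tr] <- included[tr] + 1L
    res_cnt[ho] <- res_cnt[ho] + 1L
  }
  mean_res <- res_sum / ifelse(res_cnt > 0, res_cnt, NA_integer_)
  # per-target MAD-standardized excess over the median residual
  z <- apply(mean_res, 2, function(r) {
    (r - stats::median(r, na.rm = TRUE)) / stats::mad(r, na.rm = TRUE)
  })
  z <- matrix(z, n, n_tgt)
  score <- apply(z, 1, max)
  flags <- !is.na(score) & score > threshold
  structure(list(sample_ids = X$sample_ids,
                 inclusion_count = included,
                 mean_residual = if (n_tgt == 1) drop(mean_res) else mean_res,
                 score = score,
                 outlier = flags,
                 n_cycles = as.integer(n_cycles), fraction = fraction,
                 threshold = threshold, seed = seed),
            class = "mccv_result")
}

#' @export
print.mccv_result <- function(x, ...) {
  cat(sprintf("mccv_result: %d cycles at %.0f%%, %d/%d samples flagged\n",
              x$n_cycles, 100 * x$fraction, sum(x$outlier), length(x$outlier)))
  invisible(x)
}

#' Hyperparameter and wavelength grid
#'
#' @param num_trees forest sizes to try.
#' @param max_depth tree depth limits (`0` = unlimited).
#' @param mtry features tried per split (`0` = ranger default, sqrt(p)).
#' @param k numbers of retained characteristic wavelengths.
#' @return A list of grid axes for [grid_search_select()].
#' @export
model_grid <- function(num_trees = c(100, 300), max_depth = c(0, 10),
                       mtry = 0, k = c(8, 10, 15)) {
  list(num_trees = num_trees, max_depth = max_depth, mtry = mtry, k = k)
}

#' Grid-search selection of characteristic wavelengths
#'
#' For every forest-hyperparameter combination and every fold of a k-fold
#' cross-validation on the calibration set, a full-spectrum forest is fitted
#' on the fold's training part and its impurity importances (normalised to
#' sum 1) rank the wavelengths. For each candidate count `k`, a forest
#' restricted to the fold's top-k wavelengths predicts the held-out fold;
#' the pooled CV RMSE scores the grid point. The grid point with minimal CV
#' RMSE wins; ties prefer fewer wavelengths, then fewer trees, then
#' shallower forests. Its characteristic wavelengths are the top-k of the
#' fold-averaged importances.
#'
#' Neighbouring bands of a contiguous spectrometer grid are strongly
#' correlated, so a plain top-k would spend its whole budget inside the
#' single strongest absorption region. Retention is therefore peak-style:
#' wavelengths are accepted in decreasing importance, skipping candidates
#' closer than `min_sep_nm` to an already accepted one (falling back to the
#' skipped candidates if the spectrum runs out). Set `min_sep_nm = 0` for
#' plain top-k.
#'
#' Folds are contiguous blocks after a seeded shuffle.
#'
#' @param X_cal calibration [spectrum_matrix()].
#' @param y_cal calibration target vector.
#' @param grid a [model_grid()].
#' @param k_folds number of CV folds (default 10).
#' @param min_sep_nm minimum separation between retained wavelengths (nm).
#' @param seed integer seed.
#' @return An object of class `selection_result`: chosen hyperparameters and
#'   `k`, selected wavelength indices and nm values, fold-averaged
#'   per-wavelength importances, and the CV RMSE per grid point.
#' @export
grid_search_select <- function(X_cal, y_cal, grid = model_grid(),
                               k_folds = 10L, min_sep_nm = 5, seed = 1L) {
  stopifnot_spectrum_matrix(X_cal)
  n <- nrow(X_cal$values)
  p <- ncol(X_cal$values)
  if (n < k_folds) stop("need at least k_folds calibration samples")
  if (any(grid$k > p)) stop("k exceeds the number of available wavelengths")
  if (!length(grid$num_trees) || !length(grid$k)) stop("grid must be non-empty")

  set.seed(seed)
  perm <- sample.int(n)
  fold_of <- integer(n)
  fold_of[perm] <- cut(seq_len(n), breaks = k_folds, labels = FALSE)

  hyper <- expand.grid(num_trees = grid$num_trees, max_depth = grid$max_depth,
                       mtry = grid$mtry, KEEP.OUT.ATTRS = FALSE)
  combos <- expand.grid(hyper_id = seq_len(nrow(hyper)), k = grid$k,
                        KEEP.OUT.ATTRS = FALSE)
  sq_err <- matrix(0, nrow(combos), 1)   # pooled squared error per grid point
  imp_sum <- array(0, dim = c(nrow(hyper), p))

  for (h in seq_len(nrow(hyper))) {
    nt <- hyper$num_trees[h]
    md <- hyper$max_depth[h]
    mt <- if (hyper$mtry[h] > 0) hyper$mtry[h] else NULL
    for (f in seq_len(k_folds)) {
      tr <- fold_of != f
      fit <- ranger::ranger(x = rx(X_cal$values[tr, , drop = FALSE]), y = y_cal[tr],
                            num.trees = nt, max.depth = md, mtry = mt,
                            importance = "impurity",
                            seed = seed + 1000L * h + f, num.threads = 1)
      imp <- fit$variable.importance
      imp[imp < 0] <- 0
      tot <- sum(imp)
      imp <- if (tot > 0) imp / tot else rep(1 / p, p)
      imp_sum[h, ] <- imp_sum[h, ] + imp
      for (ci in which(combos$hyper_id == h)) {
        kk <- combos$k[ci]
        top <- pick_top_separated(imp, X_cal$wavelengths, kk, min_sep_nm)
        sub <- ranger::ranger(x = rx(X_cal$values[tr, top, drop = FALSE]),
                              y = y_cal[tr], num.trees = nt, max.depth = md,
                              mtry = if (!is.null(mt)) min(mt, kk) else NULL,
                              seed = seed + 1000L * h + f, num.threads = 1)
        pred <- stats::predict(sub, rx(X_cal$values[!tr, top, drop = FALSE]),
                               num.threads = 1)$predictions
        sq_err[ci] <- sq_err[ci] + sum((pred - y_cal[!tr])^2)
      }
    }
  }
  cv_rmse <- sqrt(sq_err[, 1] / n)
  # argmin with ties broken by fewer wavelengths, fewer trees, shallower depth
  # (unlimited depth, coded 0, counts as deepest)
  depth_rank <- ifelse(hyper$max_depth[combos$hyper_id] == 0, Inf,
                       hyper$max_depth[combos$hyper_id])
  best <- order(cv_rmse, combos$k, hyper$num_trees[combos$hyper_id],
                depth_rank)[1]
  h_best <- combos$hyper_id[best]
  k_best <- combos$k[best]
  imp_mean <- imp_sum[h_best, ] / k_folds
  sel <- pick_top_separated(imp_mean, X_cal$wavelengths, k_best, min_sep_nm)

  grid_table <- cbind(hyper[combos$hyper_id, , drop = FALSE],
                      k = combos$k, cv_rmse = cv_rmse)
  rownames(grid_table) <- NULL
  structure(list(
    num_trees = hyper$num_trees[h_best],
    max_depth = hyper$max_depth[h_best],
    mtry = hyper$mtry[h_best],
    k = k_best,
    wavelength_idx = sel,
    wavelengths_nm = X_cal$wavelengths[sel],
    importance = stats::setNames(imp_mean, format(X_cal$wavelengths)),
    cv_rmse = stats::setNames(cv_rmse, NULL),
    grid_table = grid_table,
    k_folds = as.integer(k_folds), min_sep_nm = min_sep_nm, seed = seed),
    class = "selection_result")
}

# Greedy separated top-k: walk wavelengths in decreasing importance (ties to
# the lower index), accepting a candidate only if it is at least min_sep nm
# from every accepted one; if fewer than k survive, fill from the skipped
# candidates in importance order. Returns sorted indices.
pick_top_separated <- function(imp, wl, k, min_sep) {
  ord <- order(-imp, seq_along(imp))
  acc <- integer(0)
  skipped <- integer(0)
  for (j in ord) {
    if (length(acc) == k) break
    if (length(acc) && any(abs(wl[acc] - wl[j]) < min_sep)) {
      skipped <- c(skipped, j)
    } else {
      acc <- c(acc, j)
    }
  }
  if (length(acc) < k)
    acc <- c(acc, skipped[seq_len(k - length(acc))])
  sort(acc)
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result: %d trees, depth %s, k = %d wavelengths\n",
              x$num_trees, if (x$max_depth == 0) "unlimited" else x$max_depth,
              x$k))
  cat("  selected (nm):", paste(round(x$wavelengths_nm, 1), collapse = ", "), "\n")
  invisible(x)
}

#' Manually specify a wavelength selection
#'
#' Builds a `selection_result` without a grid search, for fitting a forest
#' on a chosen wavelength subset (or the full spectrum).
#'
#' @param X a [spectrum_matrix()] supplying the wavelength grid.
#' @param wavelength_idx indices of wavelengths to use (default: all).
#' @param num_trees,max_depth,mtry forest hyperparameters as in
#'   [model_grid()].
#' @return A `selection_result`.
#' @export
manual_selection <- function(X, wavelength_idx = seq_along(X$wavelengths),
                             num_trees = 300, max_depth = 0, mtry = 0) {
  stopifnot_spectrum_matrix(X)
  structure(list(num_trees = num_trees, max_depth = max_depth, mtry = mtry,
                 k = length(wavelength_idx),
                 wavelength_idx = wavelength_idx,
                 wavelengths_nm = X$wavelengths[wavelength_idx],
                 importance = NULL, cv_rmse = NULL, grid_table = NULL,
                 k_folds = NA_integer_, seed = NA_integer_),
            class = "selection_result")
}

#' Fit the final random-forest model
#'
#' Trains a forest on the calibration set restricted to the selected
#' characteristic wavelengths, with the selected hyperparameters.
#'
#' @param X_cal calibration [spectrum_matrix()] (already preprocessed).
#' @param y_cal calibration target vector.
#' @param selection a `selection_result` from [grid_search_select()] or
#'   [manual_selection()].
#' @param seed integer seed.
#' @param target name of the modelled quantity (for reports).
#' @param ss_state optional `preprocess_state` when the provenance includes
#'   column standardization; stored so new spectra can be transformed.
#' @return An object of class `model_bundle`.
#' @export
fit_rf_model <- function(X_cal, y_cal, selection, seed = 1L,
                         target = "target", ss_state = NULL) {
  stopifnot_spectrum_matrix(X_cal)
  if (!inherits(selection, "selection_result")) stop("expected a selection_result")
  idx <- selection$wavelength_idx
  mt <- if (selection$mtry > 0) min(selection$mtry, length(idx)) else NULL
  fit <- ranger::ranger(x = rx(X_cal$values[, idx, drop = FALSE]), y = y_cal,
                        num.trees = selection$num_trees,
                        max.depth = selection$max_depth, mtry = mt,
                        seed = seed, num.threads = 1)
  structure(list(model = fit,
                 wavelength_idx = idx,
                 wavelengths_nm = X_cal$wavelengths[idx],
                 grid_wavelengths = X_cal$wavelengths,
                 hyper = list(num_trees = selection$num_trees,
                              max_depth = selection$max_depth,
                              mtry = selection$mtry),
                 provenance = X_cal$provenance,
                 ss_state = ss_state,
                 seed = seed, target = target),
            class = "model_bundle")
}

#' Predict from a fitted model bundle
#'
#' @param object a `model_bundle`.
#' @param newdata a [spectrum_matrix()] on the training wavelength grid, or a
#'   plain numeric matrix/vector of spectra already on that grid. Spectra
#'   must carry the same preprocessing as the training data.
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.model_bundle <- function(object, newdata, ...) {
  if (inherits(newdata, "spectrum_matrix")) {
    if (!isTRUE(all.equal(newdata$wavelengths, object$grid_wavelengths)))
      stop("wavelength grid does not match the grid the model was trained on")
    x <- newdata$values
  } else {
    x <- if (is.matrix(newdata)) newdata else matrix(newdata, nrow = 1)
    if (ncol(x) == length(object$grid_wavelengths)) {
      # full-grid spectra: restrict below
    } else if (ncol(x) != length(object$wavelength_idx)) {
      stop("spectrum length matches neither the full grid nor the selection")
    }
  }
  if (ncol(x) == length(object$grid_wavelengths))
    x <- x[, object$wavelength_idx, drop = FALSE]
  stats::predict(object$model, rx(x), num.threads = 1)$predictions
}

#' @export
print.model_bundle <- function(x, ...) {
  cat(sprintf("model_bundle '%s': %d trees on %d wavelengths [%s]\n",
              x$target, x$hyper$num_trees, length(x$wavelength_idx),
              paste(c("raw", x$provenance), collapse = " -> ")))
  invisible(x)
}

#' Save / load a model bundle
#'
#' A bundle directory holds a JSON manifest (selected wavelengths,
#' hyperparameters, preprocessing provenance, seeds) and the serialized
#' ensemble. Loading reproduces predictions exactly.
#'
#' @param bundle a `model_bundle`.
#' @param dir directory to create/read.
#' @return `dir` (save) or the restored `model_bundle` (load).
#' @export
save_bundle <- function(bundle, dir) {
  if (!inherits(bundle, "model_bundle")) stop("expected a model_bundle")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- bundle[c("wavelength_idx", "wavelengths_nm", "grid_wavelengths",
                       "hyper", "provenance", "seed", "target")]
  manifest$has_ss_state <- !is.null(bundle$ss_state)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  saveRDS(bundle$model, file.path(dir, "ensemble.rds"))
  if (!is.null(bundle$ss_state))
    saveRDS(bundle$ss_state, file.path(dir, "ss_state.rds"))
  invisible(dir)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  structure(list(model = readRDS(file.path(dir, "ensemble.rds")),
                 wavelength_idx = as.integer(mf$wavelength_idx),
                 wavelengths_nm = as.numeric(mf$wavelengths_nm),
                 grid_wavelengths = as.numeric(mf$grid_wavelengths),
                 hyper = mf$hyper,
                 provenance = as.character(mf$provenance),
                 ss_state = if (isTRUE(mf$has_ss_state))
                   readRDS(file.path(dir, "ss_state.rds")) else NULL,
                 seed = mf$seed, target = mf$target),
            class = "model_bundle")
}
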