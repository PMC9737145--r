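#' Pixel-wise chemical concentration map
#'
#' Predicts the model target independently at every fruit pixel: each pixel's
#' spectrum is passed through the bundle's preprocessing chain (SNV and the
#' derivative act per spectrum; column standardization reuses the stored
#' calibration-set state), restricted to the selected wavelengths, and
#' predicted. Tray pixels are `NA`.
#'
#' @param cube a calibrated [spectral_cube()].
#' @param fruit logical fruit mask.
#' @param bundle a fitted `model_bundle`.
#' @return An object of class `prediction_map` (`mode = "pixel-wise"`).
#' @export
pixelwise_map <- function(cube, fruit, bundle) {
  if (!inherits(cube, "spectral_cube")) stop("expected a spectral_cube")
  if (!cube$calibrated) stop("cube must be calibrated")
  spectra <- cube_pixel_spectra(cube, fruit)
  preds <- predict_spectra(bundle, spectra, cube$wavelengths)
  vals <- matrix(NA_real_, dim(cube$values)[1], dim(cube$values)[2])
  vals[fruit] <- preds
  prediction_map(vals, "pixel-wise", bundle)
}

#' Object-wise chemical concentration map
#'
#' One prediction from the ROI mean spectrum, painted uniformly over the
#' fruit mask — the whole-fruit summary used for grading.
#'
#' @param cube a calibrated [spectral_cube()].
#' @param fruit logical fruit mask.
#' @param roi an `roi_mask` from [extract_roi()].
#' @param bundle a fitted `model_bundle`.
#' @return An object of class `prediction_map` (`mode = "object-wise"`).
#' @export
objectwise_map <- function(cube, fruit, roi, bundle) {
  if (!inherits(cube, "spectral_cube")) stop("expected a spectral_cube")
  if (!cube$calibrated) stop("cube must be calibrated")
  spec <- mean_spectrum(cube, roi)
  pred <- predict_spectra(bundle, matrix(spec, nrow = 1), cube$wavelengths)
  vals <- matrix(NA_real_, dim(cube$values)[1], dim(cube$values)[2])
  vals[fruit] <- pred
  prediction_map(vals, "object-wise", bundle)
}

# Apply the bundle's preprocessing chain to raw spectra (pixels x bands on
# the full grid) and predict.
predict_spectra <- function(bundle, spectra, wavelengths) {
  if (!isTRUE(all.equal(wavelengths, bundle$grid_wavelengths)))
    stop("wavelength grid does not match the grid the model was trained on")
  m <- spectrum_matrix(spectra, wavelengths,
                       sample_ids = sprintf("px%07d", seq_len(nrow(spectra))))
  for (step in bundle$provenance) {
    m <- switch(step,
      snv = snv(m),
      d1  = first_derivative(m),
      ss  = {
        if (is.null(bundle$ss_state))
          stop("bundle provenance includes 'ss' but no stored state")
        standardize_apply(m, bundle$ss_state)
      },
      stop("unknown preprocessing step in provenance: ", step))
  }
  predict(bundle, m)
}

prediction_map <- function(values, mode, bundle) {
  fin <- values[is.finite(values)]
  bounds <- if (length(fin)) as.numeric(stats::quantile(fin, c(0.01, 0.99)))
            else c(NA_real_, NA_real_)
  structure(list(values = values, mode = mode, bounds = bounds,
                 target = bundle$target,
                 bundle_id = paste0(bundle$target, "-", bundle$seed)),
            class = "prediction_map")
}

#' @export
print.prediction_map <- function(x, ...) {
  fin <- x$values[is.finite(x$values)]
  cat(sprintf("prediction_map (%s) of '%s': %d fruit pixels, %.1f-%.1f ug/kg\n",
              x$mode, x$target, length(fin),
              if (length(fin)) min(fin) else NA, if (length(fin)) max(fin) else NA))
  invisible(x)
}

#' Render a concentration map to PNG
#'
#' Linear colour scale between the map's bounds (defaulting to the 1st-99th
#' percentile of finite values so specular outliers do not dominate the
#' legend); pixels outside the fruit are transparent. A JSON sidecar stores
#' the bounds, mode and target so the legend is reconstructible.
#'
#' @param map a `prediction_map`.
#' @param path output PNG path.
#' @param bounds optional explicit colour-scale bounds `c(lo, hi)`.
#' @param palette colour vector (low to high).
#' @return `path`, invisibly.
#' @export
render_map <- function(map, path, bounds = map$bounds,
                       palette = grDevices::hcl.colors(256, "YlOrRd", rev = TRUE)) {
  if (!inherits(map, "prediction_map")) stop("expected a prediction_map")
  v <- map$values
  if (!any(is.finite(v))) stop("map has no finite values to render")
  if (bounds[2] <= bounds[1]) bounds[2] <- bounds[1] + 1e-9
  z <- (v - bounds[1]) / (bounds[2] - bounds[1])
  z[z < 0] <- 0; z[z > 1] <- 1
  idx <- 1L + as.integer(round(z * (length(palette) - 1L)))
  rgba <- array(0, dim = c(nrow(v), ncol(v), 4))
  ok <- is.finite(v)
  cols <- grDevices::col2rgb(palette[idx[ok]]) / 255
  for (ch in 1:3) {
    layer <- matrix(0, nrow(v), ncol(v))
    layer[ok] <- cols[ch, ]
    rgba[, , ch] <- layer
  }
  alpha <- matrix(0, nrow(v), ncol(v))
  alpha[ok] <- 1
  rgba[, , 4] <- alpha
  png::writePNG(rgba, path)
  jsonlite::write_json(list(bounds = bounds, mode = map$mode,
                            target = map$target, bundle_id = map$bundle_id),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
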