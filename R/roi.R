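#' Segment the fruit from the tray background
#'
#' Thresholds the per-pixel mean reflectance with Otsu's two-class rule and
#' keeps the largest connected foreground component. The fruit sits on a
#' near-black tray, so a bimodal brightness histogram is expected.
#'
#' @param cube a calibrated [spectral_cube()].
#' @return Logical rows x cols matrix, `TRUE` on fruit pixels.
#' @export
segment_fruit <- function(cube) {
  if (!inherits(cube, "spectral_cube")) stop("expected a spectral_cube")
  if (!cube$calibrated) stop("cube must be calibrated before segmentation")
  b <- cube_brightness(cube)
  rng <- range(b)
  if (rng[2] <= rng[1]) stop("no fruit found: uniform brightness image")
  thr <- EBImage::otsu(EBImage::Image((b - rng[1]) / (rng[2] - rng[1])))
  mask <- (b - rng[1]) / (rng[2] - rng[1]) > thr
  if (!any(mask)) stop("no fruit found")
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(mask), ncol(mask))
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  out <- lab == keep
  if (!any(out)) stop("no fruit found")
  out
}

#' Extract the moderate-reflection region of interest
#'
#' Ranks fruit pixels by brightness (mean reflectance over bands) and retains
#' the central fraction of the brightness distribution — a symmetric
#' percentile band around the median. This drops the very intense specular
#' centre and the dim fruit edge, keeping the moderate-reflection pixels
#' whose mean spectrum represents the sample.
#'
#' @param cube a calibrated [spectral_cube()].
#' @param fruit logical fruit mask from [segment_fruit()].
#' @param retain_fraction fraction of fruit pixels to retain (default 0.15).
#' @return An object of class `roi_mask`: the logical pixel mask, the
#'   retained fraction, and the percentile bounds used.
#' @export
extract_roi <- function(cube, fruit, retain_fraction = 0.15) {
  if (!inherits(cube, "spectral_cube")) stop("expected a spectral_cube")
  if (!cube$calibrated) stop("cube must be calibrated")
  if (!any(fruit)) stop("fruit mask is empty")
  if (!is.numeric(retain_fraction) || retain_fraction <= 0 || retain_fraction > 1)
    stop("retain_fraction must lie in (0, 1]")
  b <- cube_brightness(cube)
  idx <- which(fruit)                       # column-major pixel index
  n <- length(idx)
  m <- max(1L, round(retain_fraction * n))
  # order by brightness, ties broken by pixel index for determinism
  ord <- idx[order(b[idx], idx)]
  lo <- floor((n - m) / 2)
  sel <- ord[(lo + 1):(lo + m)]
  mask <- matrix(FALSE, nrow(b), ncol(b))
  mask[sel] <- TRUE
  structure(list(mask = mask,
                 retained_fraction = retain_fraction,
                 percentile_bounds = c(50 - 100 * retain_fraction / 2,
                                       50 + 100 * retain_fraction / 2)),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("roi_mask: %d pixels retained (%.0f%%, percentile band %.1f-%.1f)\n",
              sum(x$mask), 100 * x$retained_fraction,
              x$percentile_bounds[1], x$percentile_bounds[2]))
  invisible(x)
}

#' Mean ROI spectrum
#'
#' Arithmetic mean, per band, over the retained pixels.
#'
#' @param cube a [spectral_cube()].
#' @param roi an `roi_mask` from [extract_roi()], or a plain logical matrix.
#' @return Numeric vector of length `bands`.
#' @export
mean_spectrum <- function(cube, roi) {
  if (!inherits(cube, "spectral_cube")) stop("expected a spectral_cube")
  mask <- if (inherits(roi, "roi_mask")) roi$mask else roi
  if (!is.logical(mask) || !all(dim(mask) == dim(cube$values)[1:2]))
    stop("roi must be a logical mask matching the cube's pixel grid")
  if (!any(mask)) stop("ROI is empty")
  colMeans(cube_pixel_spectra(cube, mask))
}

#' Write a binary mask as a PNG file
#'
#' @param mask logical matrix.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask * 1, path)
  invisible(path)
}
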