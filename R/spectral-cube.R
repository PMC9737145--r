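#' Construct a hyperspectral cube
#'
#' A `spectral_cube` is a rows x cols x bands array of reflectance (or raw
#' sensor counts before calibration) with its wavelength grid. Calibrated
#' cubes hold integer-scaled relative reflectance on the 0-10000 scale, where
#' 10000 corresponds to 100% reflectance against the white reference.
#'
#' @param values 3-D numeric array, band axis last.
#' @param wavelengths strictly increasing nm vector, length equal to the band
#'   axis extent.
#' @param calibrated logical; `TRUE` once dark/white reflectance correction
#'   has been applied.
#' @param metadata optional named list of free-form acquisition notes.
#' @return An object of class `spectral_cube`.
#' @export
spectral_cube <- function(values, wavelengths, calibrated = FALSE,
                          metadata = list()) {
  if (length(dim(values)) != 3L)
    stop("values must be a 3-D array (rows x cols x bands)")
  if (dim(values)[3] != length(wavelengths))
    stop("band axis extent (", dim(values)[3],
         ") does not match wavelength count (", length(wavelengths), ")")
  if (length(wavelengths) >= 2 && any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  if (calibrated && (min(values) < 0 || max(values) > 10000))
    stop("calibrated cube values must lie in [0, 10000]")
  structure(list(values = values,
                 wavelengths = as.numeric(wavelengths),
                 calibrated = isTRUE(calibrated),
                 metadata = metadata),
            class = "spectral_cube")
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("spectral_cube: %d x %d pixels, %d bands (%.1f-%.1f nm), %s\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths),
              if (x$calibrated) "calibrated" else "raw"))
  invisible(x)
}

#' Dark/white reflectance calibration
#'
#' Converts raw counts to relative reflectance with the standard two-point
#' correction R = (R0 - D) / (W - D), where D is a dark frame (lens covered)
#' and W a white reference (near-100% reflective Teflon sheet). The result is
#' scaled to 10000, rounded to integers (round-half-to-even) and clipped to
#' \[0, 10000\].
#'
#' @param raw an uncalibrated [spectral_cube()].
#' @param refs a [reference_frames()] object holding the dark and white frames.
#' @return A calibrated `spectral_cube` of the same dimensions.
#' @export
calibrate_reflectance <- function(raw, refs) {
  if (!inherits(raw, "spectral_cube")) stop("expected a spectral_cube")
  if (raw$calibrated) stop("cube is already calibrated")
  d <- dim(raw$values)
  D <- expand_reference(refs$dark, d)
  W <- expand_reference(refs$white, d)
  bad <- which(W <= D)
  if (length(bad)) {
    ix <- arrayInd(bad[1], d)
    stop(sprintf("white <= dark at pixel (row %d, col %d, band %d)",
                 ix[1], ix[2], ix[3]))
  }
  r <- 10000 * (raw$values - D) / (W - D)
  r <- round(r)                       # round half to even, per IEC 60559
  r[r < 0] <- 0
  r[r > 10000] <- 10000
  spectral_cube(r, raw$wavelengths, calibrated = TRUE, metadata = raw$metadata)
}

#' Dark and white reference frames
#'
#' @param dark,white dark/white reference data. Each may be a scalar, a
#'   per-band vector (length = bands), a rows x cols matrix, or a full
#'   rows x cols x bands array; lower-dimensional forms are broadcast over
#'   the missing axes during calibration.
#' @return An object of class `reference_frames`.
#' @export
reference_frames <- function(dark, white) {
  structure(list(dark = dark, white = white), class = "reference_frames")
}

# Broadcast a reference (scalar / band vector / pixel matrix / full array)
# to the cube dimensions d = c(rows, cols, bands).
expand_reference <- function(x, d) {
  if (is.array(x) && length(dim(x)) == 3L) {
    if (!all(dim(x) == d)) stop("reference frame dimensions do not match cube")
    return(x)
  }
  if (is.matrix(x)) {
    if (!all(dim(x) == d[1:2])) stop("reference frame dimensions do not match cube")
    return(array(rep(as.vector(x), d[3]), dim = d))
  }
  if (length(x) == 1L) return(array(x, dim = d))
  if (length(x) == d[3]) return(aperm(array(x, dim = d[c(3, 1, 2)]), c(2, 3, 1)))
  stop("reference frame must be scalar, per-band vector, pixel matrix, or full array")
}

# Per-pixel mean reflectance over bands (the brightness image).
cube_brightness <- function(cube) {
  rowMeans(matrix(cube$values, prod(dim(cube$values)[1:2]), dim(cube$values)[3]),
           na.rm = FALSE) |>
    matrix(dim(cube$values)[1], dim(cube$values)[2])
}

# Flatten cube to a pixels x bands matrix for the pixels where mask is TRUE.
cube_pixel_spectra <- function(cube, mask) {
  d <- dim(cube$values)
  flat <- matrix(cube$values, d[1] * d[2], d[3])
  flat[as.vector(mask), , drop = FALSE]
}
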