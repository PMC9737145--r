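#' Standard normal variate transform
#'
#' Centres and scales each spectrum (row) to mean 0 and standard deviation 1,
#' using the population (n-denominator) standard deviation. SNV removes
#' per-sample multiplicative scatter and additive baseline offsets exactly:
#' `snv(a * x + b)` equals `snv(x)` for any `a > 0`.
#'
#' @param m a [spectrum_matrix()].
#' @param population logical; use the population standard deviation (default)
#'   or the sample (n-1) convention.
#' @return A transformed `spectrum_matrix` with provenance tag `"snv"`.
#' @export
snv <- function(m, population = TRUE) {
  stopifnot_spectrum_matrix(m)
  x <- m$values
  mu <- rowMeans(x)
  cx <- x - mu
  n <- ncol(x)
  ss <- rowSums(cx^2)
  sd <- sqrt(ss / if (population) n else n - 1L)
  zero <- which(sd == 0)
  if (length(zero))
    stop("constant spectrum (zero variance) for sample ",
         paste(m$sample_ids[zero], collapse = ", "))
  sm_with(m, cx / sd, "snv")
}

#' Savitzky-Golay first derivative
#'
#' First derivative of reflectance with respect to wavelength (per-nm units),
#' estimated by local least-squares polynomial fits: at each wavelength a
#' polynomial of the given order is fitted over a centred window and its
#' slope is taken. Edge columns use the window truncated at the grid
#' boundary. Exact for polynomials up to the fit order, so constants map to
#' zero and a linear ramp to its slope. Works on non-uniform grids.
#'
#' @param m a [spectrum_matrix()].
#' @param window odd window length in points (default 7).
#' @param polyorder polynomial order (default 2); must be `< window`.
#' @return A `spectrum_matrix` of the same shape with provenance tag `"d1"`.
#' @export
first_derivative <- function(m, window = 7L, polyorder = 2L) {
  stopifnot_spectrum_matrix(m)
  p <- ncol(m$values)
  if (p < 3) stop("need at least 3 wavelengths")
  if (window %% 2 != 1 || window < polyorder + 1)
    stop("window must be odd and exceed the polynomial order")
  if (p < window) stop("fewer wavelengths (", p, ") than window (", window, ")")
  W <- sg_derivative_weights(m$wavelengths, window, polyorder)
  sm_with(m, m$values %*% W, "d1")
}

# Column j of the returned p x p matrix holds the weights that map a spectrum
# to its derivative at wavelength j: slope of the least-squares polynomial of
# degree `order` over the window centred (or truncated) at j.
sg_derivative_weights <- function(wl, window, order) {
  p <- length(wl)
  h <- (window - 1L) %/% 2L
  W <- matrix(0, p, p)
  for (j in seq_len(p)) {
    idx <- max(1L, j - h):min(p, j + h)
    A <- outer(wl[idx] - wl[j], 0:order, "^")
    # derivative at wl[j] = coefficient of the linear term
    coefs <- solve(crossprod(A), t(A))
    W[idx, j] <- coefs[2L, ]
  }
  W
}

#' Column-wise standardization: learn calibration statistics
#'
#' Learns per-wavelength mean and population standard deviation on the
#' calibration set only, so no validation information leaks into the
#' transform.
#'
#' @param calibration a [spectrum_matrix()] with at least 2 samples.
#' @return A `preprocess_state` holding the per-wavelength statistics.
#' @export
standardize_fit <- function(calibration) {
  stopifnot_spectrum_matrix(calibration)
  x <- calibration$values
  if (nrow(x) < 2) stop("need at least 2 calibration samples")
  mu <- colMeans(x)
  sd <- sqrt(colMeans(sweep(x, 2, mu)^2))
  zero <- which(sd == 0)
  if (length(zero))
    stop("zero-variance column at wavelength ",
         paste(format(calibration$wavelengths[zero]), collapse = ", "), " nm")
  structure(list(method = "ss", mean = mu, sd = sd,
                 wavelengths = calibration$wavelengths),
            class = "preprocess_state")
}

#' Apply learned standardization
#'
#' @param m a [spectrum_matrix()] on the same wavelength grid as the state.
#' @param state a `preprocess_state` from [standardize_fit()].
#' @return A `spectrum_matrix` with provenance tag `"ss"`.
#' @export
standardize_apply <- function(m, state) {
  stopifnot_spectrum_matrix(m)
  if (!inherits(state, "preprocess_state")) stop("expected a preprocess_state")
  if (!isTRUE(all.equal(m$wavelengths, state$wavelengths)))
    stop("wavelength grid does not match the grid the state was fitted on")
  sm_with(m, sweep(sweep(m$values, 2, state$mean), 2, state$sd, "/"), "ss")
}

#' Apply a named preprocessing method
#'
#' Convenience dispatcher over the pre-treatments compared in this pipeline:
#' `"raw"` (identity), `"snv"`, `"d1"`, and `"ss"`. For `"ss"`, statistics
#' are learned on `calibration` (defaulting to `m` itself) and the fitted
#' state is returned alongside so validation data can be transformed without
#' leakage.
#'
#' @param m a [spectrum_matrix()].
#' @param method one of `"raw"`, `"snv"`, `"d1"`, `"ss"`.
#' @param calibration calibration `spectrum_matrix` used to fit `"ss"`
#'   statistics; ignored by the stateless methods.
#' @param state optional pre-fitted `preprocess_state` for `"ss"`.
#' @return List with elements `matrix` (the transformed `spectrum_matrix`)
#'   and `state` (`NULL` unless `method = "ss"`).
#' @export
preprocess_apply <- function(m, method = c("raw", "snv", "d1", "ss"),
                             calibration = m, state = NULL) {
  method <- match.arg(method)
  switch(method,
    raw = list(matrix = m, state = NULL),
    snv = list(matrix = snv(m), state = NULL),
    d1  = list(matrix = first_derivative(m), state = NULL),
    ss  = {
      if (is.null(state)) state <- standardize_fit(calibration)
      list(matrix = standardize_apply(m, state), state = state)
    })
}
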