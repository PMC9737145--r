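#' Construct a spectrum matrix
#'
#' A `spectrum_matrix` holds mean reflectance spectra for a set of samples:
#' a numeric samples x wavelengths matrix, the wavelength grid in nm, sample
#' identifiers, and an append-only provenance record of the preprocessing
#' steps applied so far.
#'
#' @param values numeric matrix, samples in rows, wavelengths in columns.
#' @param wavelengths strictly increasing numeric vector of band centres (nm),
#'   one per column.
#' @param sample_ids character vector of unique sample identifiers, one per
#'   row. Defaults to `"S001"`, `"S002"`, ...
#' @param provenance character vector of preprocessing tags already applied
#'   (normally empty; steps append their own tags).
#' @return An object of class `spectrum_matrix`.
#' @export
spectrum_matrix <- function(values, wavelengths,
                            sample_ids = sprintf("S%03d", seq_len(nrow(values))),
                            provenance = character()) {
  values <- as.matrix(values)
  if (ncol(values) != length(wavelengths))
    stop("column count (", ncol(values), ") does not match wavelength count (",
         length(wavelengths), ")")
  if (length(wavelengths) >= 2 && any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  if (length(sample_ids) != nrow(values))
    stop("sample_ids length does not match row count")
  if (anyDuplicated(sample_ids))
    stop("sample_ids must be unique")
  rownames(values) <- sample_ids
  structure(list(values = values,
                 wavelengths = as.numeric(wavelengths),
                 sample_ids = as.character(sample_ids),
                 provenance = as.character(provenance)),
            class = "spectrum_matrix")
}

#' @export
print.spectrum_matrix <- function(x, ...) {
  cat(sprintf("spectrum_matrix: %d samples x %d wavelengths (%.1f-%.1f nm)\n",
              nrow(x$values), ncol(x$values),
              min(x$wavelengths), max(x$wavelengths)))
  prov <- if (length(x$provenance)) paste(x$provenance, collapse = " -> ") else "raw"
  cat("  preprocessing:", prov, "\n")
  invisible(x)
}

#' @export
dim.spectrum_matrix <- function(x) dim(x$values)

#' Subset samples of a spectrum matrix
#'
#' @param m a [spectrum_matrix()].
#' @param i sample ids, or a logical/integer row index.
#' @return A `spectrum_matrix` with the selected rows, same provenance.
#' @export
subset_samples <- function(m, i) {
  stopifnot_spectrum_matrix(m)
  sm_subset(m, i)
}

# Internal: subset rows of a spectrum_matrix by ids or logical/integer index.
sm_subset <- function(m, i) {
  if (is.character(i)) {
    j <- match(i, m$sample_ids)
    if (anyNA(j)) stop("unknown sample ids: ", paste(i[is.na(j)], collapse = ", "))
    i <- j
  }
  spectrum_matrix(m$values[i, , drop = FALSE], m$wavelengths,
                  m$sample_ids[i], m$provenance)
}

# Internal: append a provenance tag, returning a new spectrum_matrix.
sm_with <- function(m, values, tag) {
  spectrum_matrix(values, m$wavelengths, m$sample_ids, c(m$provenance, tag))
}

stopifnot_spectrum_matrix <- function(m) {
  if (!inherits(m, "spectrum_matrix")) stop("expected a spectrum_matrix")
  invisible(m)
}
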