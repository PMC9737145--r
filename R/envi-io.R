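#' Read an ENVI hyperspectral cube
#'
#' Reads the common ENVI format: a `key = value` text header (`.hdr`) next to
#' a flat binary file. BIL, BIP and BSQ interleaves and integer/float data
#' types are supported; the header must carry a `wavelength = {...}` list.
#'
#' @param path path to the binary file, or to the `.hdr` header.
#' @return A [spectral_cube()]. The `calibrated` flag is restored from the
#'   header's `reflectance scale factor` convention: integer data with
#'   `data type` 12 (or a `calibrated = 1` note) is treated as calibrated.
#' @export
read_envi <- function(path) {
  paths <- envi_paths(path)
  if (!file.exists(paths$hdr)) stop("ENVI header not found: ", paths$hdr)
  if (!file.exists(paths$bin)) stop("ENVI binary not found: ", paths$bin)
  hdr <- parse_envi_header(paths$hdr)
  need <- c("samples", "lines", "bands", "data type", "interleave")
  miss <- setdiff(need, names(hdr))
  if (length(miss)) stop("ENVI header missing field(s): ", paste(miss, collapse = ", "))
  if (is.null(hdr[["wavelength"]]))
    stop("ENVI header has no wavelength list")
  ns <- as.integer(hdr[["samples"]]); nl <- as.integer(hdr[["lines"]])
  nb <- as.integer(hdr[["bands"]])
  wl <- as.numeric(hdr[["wavelength"]])
  if (length(wl) != nb) stop("wavelength list length does not match bands")
  dt <- as.integer(hdr[["data type"]])
  sz <- envi_type_size(dt)
  expect <- as.numeric(ns) * nl * nb * sz$bytes
  actual <- file.size(paths$bin)
  if (actual != expect)
    stop(sprintf("ENVI binary size mismatch: header implies %.0f bytes, file has %.0f",
                 expect, actual))
  con <- file(paths$bin, "rb")
  on.exit(close(con))
  v <- readBin(con, what = sz$what, n = ns * nl * nb, size = sz$bytes,
               signed = sz$signed, endian = "little")
  storage.mode(v) <- "double"
  interleave <- tolower(hdr[["interleave"]])
  # file layout is row-major within each frame; map to rows x cols x bands
  vals <- switch(interleave,
    bsq = aperm(array(v, dim = c(ns, nl, nb)), c(2, 1, 3)),
    bil = aperm(array(v, dim = c(ns, nb, nl)), c(3, 1, 2)),
    bip = aperm(array(v, dim = c(nb, ns, nl)), c(3, 2, 1)),
    stop("unsupported interleave: ", interleave))
  calibrated <- identical(hdr[["calibrated"]], "1")
  spectral_cube(vals, wl, calibrated = calibrated,
                metadata = list(description = hdr[["description"]]))
}

#' Write an ENVI hyperspectral cube
#'
#' @param cube a [spectral_cube()].
#' @param path output path for the binary file; the header is written next to
#'   it as `<path>.hdr`.
#' @param interleave one of `"bil"` (default), `"bsq"`, `"bip"`.
#' @return `path`, invisibly.
#' @export
write_envi <- function(cube, path, interleave = c("bil", "bsq", "bip")) {
  interleave <- match.arg(interleave)
  if (!inherits(cube, "spectral_cube")) stop("expected a spectral_cube")
  v <- cube$values
  d <- dim(v)
  int_ok <- all(v == round(v)) && min(v) >= 0 && max(v) <= 65535
  dt <- if (int_ok) 12L else 5L
  sz <- envi_type_size(dt)
  flat <- switch(interleave,
    bsq = as.vector(aperm(v, c(2, 1, 3))),
    bil = as.vector(aperm(v, c(2, 3, 1))),
    bip = as.vector(aperm(v, c(3, 2, 1))))
  con <- file(path, "wb")
  if (dt == 12L) {
    writeBin(as.integer(flat), con, size = 2, endian = "little")
  } else {
    writeBin(as.double(flat), con, size = 8, endian = "little")
  }
  close(con)
  hdr <- c(
    "ENVI",
    "description = {aromahsi spectral cube}",
    paste0("samples = ", d[2]),
    paste0("lines = ", d[1]),
    paste0("bands = ", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    paste0("data type = ", dt),
    paste0("interleave = ", interleave),
    "byte order = 0",
    paste0("calibrated = ", if (cube$calibrated) "1" else "0"),
    paste0("wavelength = {", paste(format(cube$wavelengths, digits = 15,
                                          trim = TRUE), collapse = ", "), "}"))
  writeLines(hdr, paste0(path, ".hdr"))
  invisible(path)
}

envi_paths <- function(path) {
  if (grepl("\\.hdr$", path)) {
    list(hdr = path, bin = sub("\\.hdr$", "", path))
  } else {
    list(hdr = paste0(path, ".hdr"), bin = path)
  }
}

envi_type_size <- function(dt) {
  switch(as.character(dt),
    "1"  = list(what = "integer", bytes = 1L, signed = FALSE),
    "2"  = list(what = "integer", bytes = 2L, signed = TRUE),
    "3"  = list(what = "integer", bytes = 4L, signed = TRUE),
    "4"  = list(what = "double",  bytes = 4L, signed = TRUE),
    "5"  = list(what = "double",  bytes = 8L, signed = TRUE),
    "12" = list(what = "integer", bytes = 2L, signed = FALSE),
    stop("unsupported ENVI data type: ", dt))
}

# Parse the key=value ENVI header dialect, including brace-delimited lists
# spanning multiple lines.
parse_envi_header <- function(hdr_path) {
  txt <- paste(readLines(hdr_path, warn = FALSE), collapse = "\n")
  out <- list()
  # join multi-line {...} blocks, then split into logical lines
  lines <- character()
  buf <- ""
  depth <- 0L
  for (ch in strsplit(txt, "", fixed = TRUE)[[1]]) {
    if (ch == "{") depth <- depth + 1L
    if (ch == "}") depth <- depth - 1L
    if (ch == "\n" && depth == 0L) {
      lines <- c(lines, buf); buf <- ""
    } else {
      buf <- paste0(buf, if (ch == "\n") " " else ch)
    }
  }
  if (nzchar(buf)) lines <- c(lines, buf)
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) next
    key <- tolower(trimws(sub("=.*$", "", ln)))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (grepl("^\\{", val)) {
      val <- gsub("^\\{|\\}$", "", val)
      if (key %in% c("wavelength", "fwhm"))
        val <- as.numeric(trimws(strsplit(val, ",")[[1]]))
      else
        val <- trimws(val)
    }
    out[[key]] <- val
  }
  out
}
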