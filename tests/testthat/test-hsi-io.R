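make_cube <- function(vals, wl = seq(400, 1000, length.out = dim(vals)[3]),
                      calibrated = FALSE) {
  spectral_cube(vals, wl, calibrated = calibrated)
}

test_that("ENVI write/read round-trips bit-identically", {
  # integer-valued cube -> uint16 path
  set.seed(1)
  v <- array(sample(0:10000, 5 * 4 * 6, replace = TRUE), dim = c(5, 4, 6))
  cube <- make_cube(v, calibrated = TRUE)
  path <- tempfile(fileext = ".raw")
  write_envi(cube, path)
  back <- read_envi(path)
  expect_identical(back$values, cube$values + 0)  # numeric compare
  expect_equal(back$wavelengths, cube$wavelengths)
  expect_true(back$calibrated)
  # non-integer cube -> float64 path
  vf <- v + 0.25
  cubef <- make_cube(vf)
  pathf <- tempfile(fileext = ".raw")
  write_envi(cubef, pathf)
  backf <- read_envi(pathf)
  expect_identical(backf$values, cubef$values)
  expect_false(backf$calibrated)
})

test_that("all interleaves decode to the same in-memory cube", {
  set.seed(2)
  v <- array(sample(0:10000, 7 * 5 * 9, replace = TRUE), dim = c(7, 5, 9))
  cube <- make_cube(v)
  got <- lapply(c("bil", "bsq", "bip"), function(il) {
    p <- tempfile(fileext = paste0(".", il))
    write_envi(cube, p, interleave = il)
    read_envi(p)$values
  })
  expect_identical(got[[1]], got[[2]])
  expect_identical(got[[1]], got[[3]])
})

test_that("header/binary inconsistencies are format errors", {
  set.seed(3)
  v <- array(sample(0:100, 4 * 4 * 5, replace = TRUE), dim = c(4, 4, 5))
  path <- tempfile(fileext = ".raw")
  write_envi(make_cube(v), path)
  # truncate the binary: size mismatch
  bin <- readBin(path, "raw", file.size(path))
  writeBin(bin[-seq_len(10)], path)
  expect_error(read_envi(path), "size mismatch")
  # remove the wavelength list
  write_envi(make_cube(v), path)
  hdr <- readLines(paste0(path, ".hdr"))
  writeLines(hdr[!grepl("^wavelength", hdr)], paste0(path, ".hdr"))
  expect_error(read_envi(path), "wavelength")
  expect_error(read_envi(tempfile()), "not found")
})

test_that("reflectance correction identities hold on integer fixtures", {
  d <- c(6, 6, 4)
  D <- array(100, dim = d)
  W <- array(4100, dim = d)
  refs <- reference_frames(D, W)
  wl <- seq(400, 1000, length.out = d[3])
  r_of <- function(raw) calibrate_reflectance(
    spectral_cube(raw, wl), refs)$values
  expect_true(all(r_of(W) == 10000))
  expect_true(all(r_of(D) == 0))
  expect_true(all(r_of((W + D) / 2) == 5000))
})

test_that("calibration is invariant to a common positive rescaling", {
  set.seed(4)
  d <- c(5, 5, 3)
  D <- array(runif(prod(d), 50, 120), dim = d)
  W <- array(runif(prod(d), 3000, 4000), dim = d)
  R0 <- D + (W - D) * array(runif(prod(d)), dim = d)
  wl <- c(400, 700, 1000)
  r1 <- calibrate_reflectance(spectral_cube(R0, wl),
                              reference_frames(D, W))$values
  r2 <- calibrate_reflectance(spectral_cube(3.7 * R0, wl),
                              reference_frames(3.7 * D, 3.7 * W))$values
  expect_equal(r1, r2)
})

test_that("calibration rejects bad references and double application", {
  d <- c(3, 3, 2)
  W <- array(1000, dim = d)
  D <- array(100, dim = d)
  D[2, 3, 1] <- 2000  # white below dark at one pixel
  cube <- spectral_cube(array(500, dim = d), c(400, 500))
  expect_error(calibrate_reflectance(cube, reference_frames(D, W)),
               "row 2, col 3, band 1")
  D[2, 3, 1] <- 100
  cal <- calibrate_reflectance(cube, reference_frames(D, W))
  expect_error(calibrate_reflectance(cal, reference_frames(D, W)),
               "already calibrated")
})

test_that("per-band reference vectors broadcast like full frames", {
  set.seed(5)
  d <- c(4, 4, 3)
  dark_v <- c(80, 90, 100)
  white_v <- c(4000, 4200, 4400)
  R0 <- array(runif(prod(d), 200, 3000), dim = d)
  cube <- spectral_cube(R0, c(400, 600, 800))
  full <- reference_frames(
    aromahsi:::expand_reference(dark_v, d),
    aromahsi:::expand_reference(white_v, d))
  vec <- reference_frames(dark_v, white_v)
  expect_identical(calibrate_reflectance(cube, vec)$values,
                   calibrate_reflectance(cube, full)$values)
})

test_that("fruit segmentation finds the disk and keeps the largest object", {
  cfg <- tiny_config(seed = 12)
  gen <- generate_spectra(cfg)
  cb <- generate_cube(cfg, gen$truth, "S003")
  cal <- calibrate_reflectance(cb$cube, cb$refs)
  mask <- segment_fruit(cal)
  # agreement with the generator's disk within a 1-pixel boundary band
  sz <- cfg$image_size; cx <- (sz + 1) / 2
  rad <- sqrt(outer((seq_len(sz) - cx)^2, (seq_len(sz) - cx)^2, "+"))
  interior <- rad <= cfg$fruit_radius - 1
  exterior <- rad > cfg$fruit_radius + 1
  expect_true(all(mask[interior]))
  expect_true(!any(mask[exterior]))

  # all-dark cube: nothing to segment
  dark <- spectral_cube(array(0, dim = c(8, 8, 3)), c(400, 500, 600),
                        calibrated = TRUE)
  expect_error(segment_fruit(dark), "no fruit found")
  expect_error(segment_fruit(spectral_cube(array(1, c(4, 4, 2)), c(400, 500))),
               "calibrated")

  # two disks, one larger: only the larger is retained
  v <- array(0, dim = c(40, 40, 3))
  for (b in 1:3) {
    img <- matrix(0, 40, 40)
    img[sqrt(outer((1:40 - 12)^2, (1:40 - 12)^2, "+")) <= 8] <- 6000
    img[sqrt(outer((1:40 - 30)^2, (1:40 - 30)^2, "+")) <= 4] <- 6000
    v[, , b] <- img
  }
  two <- spectral_cube(v, c(400, 500, 600), calibrated = TRUE)
  m2 <- segment_fruit(two)
  expect_true(m2[12, 12])
  expect_false(m2[30, 30])
})

test_that("ROI is the central brightness percentile band of the fruit", {
  cfg <- tiny_config(seed = 13)
  gen <- generate_spectra(cfg)
  cb <- generate_cube(cfg, gen$truth, "S004")
  cal <- calibrate_reflectance(cb$cube, cb$refs)
  fruit <- cb$fruit

  # retain_fraction = 1 returns the fruit mask itself
  all_roi <- extract_roi(cal, fruit, retain_fraction = 1)
  expect_identical(all_roi$mask, fruit)

  roi <- extract_roi(cal, fruit, retain_fraction = 0.15)
  n <- sum(fruit); m <- sum(roi$mask)
  expect_lte(abs(m - round(0.15 * n)), 1)
  expect_true(all(fruit[roi$mask]))  # subset of the fruit

  # sort-based oracle: retained pixels occupy the central band exactly
  b <- aromahsi:::cube_brightness(cal)
  idx <- which(fruit)
  ord <- idx[order(b[idx], idx)]
  lo <- floor((n - m) / 2)
  oracle <- sort(ord[(lo + 1):(lo + m)])
  expect_identical(which(roi$mask), oracle)

  # the band excludes the bright centre and the dim rim on shaded fruit
  expect_lt(max(b[roi$mask]), max(b[fruit]))
  expect_gt(min(b[roi$mask]), min(b[fruit]))

  expect_error(extract_roi(cal, fruit, retain_fraction = 0), "retain_fraction")
  expect_error(extract_roi(cal, fruit, retain_fraction = 1.2), "retain_fraction")
})

test_that("ROI selection is invariant under an affine brightness rescaling", {
  cfg <- tiny_config(seed = 14, noise_sd = 0)
  gen <- generate_spectra(cfg)
  cb <- generate_cube(cfg, gen$truth, "S006")
  cal <- calibrate_reflectance(cb$cube, cb$refs)
  roi1 <- extract_roi(cal, cb$fruit)
  scaled <- spectral_cube(0.5 * cal$values + 700, cal$wavelengths,
                          calibrated = TRUE)
  roi2 <- extract_roi(scaled, cb$fruit)
  expect_identical(roi1$mask, roi2$mask)
})

test_that("mean_spectrum averages retained pixels per band", {
  wl <- c(400, 500, 600)
  v <- array(0, dim = c(2, 2, 3))
  s <- c(1000, 4000, 9000)
  v[1, 1, ] <- s
  v[1, 2, ] <- 10000 - s
  cube <- spectral_cube(v, wl, calibrated = TRUE)
  one <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  expect_equal(mean_spectrum(cube, one), s)
  two <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2)
  expect_equal(mean_spectrum(cube, two), c(5000, 5000, 5000))
  full <- matrix(TRUE, 2, 2)
  flat <- aromahsi:::cube_pixel_spectra(cube, full)
  expect_equal(mean_spectrum(cube, full), colMeans(flat))
  expect_error(mean_spectrum(cube, matrix(FALSE, 2, 2)), "empty")
})
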