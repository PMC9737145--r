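# A fitted bundle + cube pair on the tiny configuration, shared across tests.
map_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- tiny_config(seed = 25)
    gen <- generate_spectra(cfg)
    m <- snv(gen$matrix)
    y <- stats::setNames(gen$truth$alcohol, gen$truth$sample_id)
    b <- fit_rf_model(m, y, manual_selection(m, num_trees = 150), seed = 25,
                      target = "alcohol")
    cache <<- list(cfg = cfg, gen = gen, bundle = b)
    cache
  }
})

test_that("pixel-wise and object-wise maps agree exactly on uniform cubes", {
  fx <- map_fixture()
  cfg_u <- tiny_config(seed = 25, specular_gain = 0, edge_falloff = 0,
                       noise_sd = 0)
  gen_u <- generate_spectra(cfg_u)  # same seed: same truth layout
  cb <- generate_cube(cfg_u, gen_u$truth, "S010")
  cal <- calibrate_reflectance(cb$cube, cb$refs)
  fruit <- cb$fruit
  roi <- extract_roi(cal, fruit)
  pw <- pixelwise_map(cal, fruit, fx$bundle)
  ow <- objectwise_map(cal, fruit, roi, fx$bundle)
  expect_identical(pw$mode, "pixel-wise")
  expect_identical(ow$mode, "object-wise")
  # a spatially uniform fruit gives the same prediction everywhere
  expect_equal(pw$values[fruit], ow$values[fruit], tolerance = 1e-12)
  # NA exactly outside the fruit
  expect_true(all(is.na(pw$values[!fruit])))
  expect_true(all(is.finite(pw$values[fruit])))
})

test_that("object-wise map is the ROI-mean prediction painted uniformly", {
  fx <- map_fixture()
  cb <- generate_cube(fx$cfg, fx$gen$truth, "S012")
  cal <- calibrate_reflectance(cb$cube, cb$refs)
  roi <- extract_roi(cal, cb$fruit)
  ow <- objectwise_map(cal, cb$fruit, roi, fx$bundle)
  direct <- aromahsi:::predict_spectra(fx$bundle,
                                       matrix(mean_spectrum(cal, roi), 1),
                                       cal$wavelengths)
  vals <- unique(ow$values[cb$fruit])
  expect_length(vals, 1)
  expect_equal(vals, direct)
  # determinism across regenerated cubes of the same sample
  cb2 <- generate_cube(fx$cfg, fx$gen$truth, "S012")
  cal2 <- calibrate_reflectance(cb2$cube, cb2$refs)
  ow2 <- objectwise_map(cal2, cb2$fruit, extract_roi(cal2, cb2$fruit), fx$bundle)
  expect_identical(ow$values, ow2$values)
})

test_that("ROI mean of the pixel-wise map tracks the object-wise value", {
  fx <- map_fixture()
  cb <- generate_cube(fx$cfg, fx$gen$truth, "S015")
  cal <- calibrate_reflectance(cb$cube, cb$refs)
  roi <- extract_roi(cal, cb$fruit)
  pw <- pixelwise_map(cal, cb$fruit, fx$bundle)
  ow <- objectwise_map(cal, cb$fruit, roi, fx$bundle)
  ow_val <- ow$values[cb$fruit][1]
  expect_lt(abs(mean(pw$values[roi$mask]) - ow_val) / ow_val, 0.05)
})

test_that("a planted radial gradient shows up with the right orientation", {
  fx <- map_fixture()
  # alcohol rises towards the rim
  cb <- generate_cube(fx$cfg, fx$gen$truth, "S018", conc_gradient = 0.6)
  cal <- calibrate_reflectance(cb$cube, cb$refs)
  pw <- pixelwise_map(cal, cb$fruit, fx$bundle)
  sz <- fx$cfg$image_size; R <- fx$cfg$fruit_radius
  cx <- (sz + 1) / 2
  rad <- sqrt(outer((seq_len(sz) - cx)^2, (seq_len(sz) - cx)^2, "+"))
  center <- mean(pw$values[rad <= 0.4 * R])
  edge <- mean(pw$values[rad > 0.75 * R & rad <= 0.95 * R])
  expect_gt(edge, center)
})

test_that("object-wise predictions average close to the true mean content", {
  fx <- map_fixture()
  ids <- fx$gen$truth$sample_id[1:12]
  ow <- vapply(ids, function(sid) {
    cb <- generate_cube(fx$cfg, fx$gen$truth, sid)
    cal <- calibrate_reflectance(cb$cube, cb$refs)
    roi <- extract_roi(cal, cb$fruit)
    objectwise_map(cal, cb$fruit, roi, fx$bundle)$values[cb$fruit][1]
  }, numeric(1))
  truth <- fx$gen$truth$alcohol[match(ids, fx$gen$truth$sample_id)]
  expect_lt(abs(mean(ow) - mean(truth)) / mean(truth), 0.10)
})

test_that("maps ignore tray content and demand calibrated input", {
  fx <- map_fixture()
  cb <- generate_cube(fx$cfg, fx$gen$truth, "S002")
  cal <- calibrate_reflectance(cb$cube, cb$refs)
  pw1 <- pixelwise_map(cal, cb$fruit, fx$bundle)
  v2 <- cal$values
  tray3 <- array(rep(!cb$fruit, dim(v2)[3]), dim = dim(v2))
  v2[tray3] <- 9999
  cal2 <- spectral_cube(v2, cal$wavelengths, calibrated = TRUE)
  pw2 <- pixelwise_map(cal2, cb$fruit, fx$bundle)
  expect_identical(pw1$values[cb$fruit], pw2$values[cb$fruit])
  expect_error(pixelwise_map(cb$cube, cb$fruit, fx$bundle), "calibrated")
})

test_that("rendering writes a faithful PNG and sidecar", {
  fx <- map_fixture()
  cb <- generate_cube(fx$cfg, fx$gen$truth, "S009")
  cal <- calibrate_reflectance(cb$cube, cb$refs)
  pw <- pixelwise_map(cal, cb$fruit, fx$bundle)
  path <- tempfile(fileext = ".png")
  render_map(pw, path)
  img <- png::readPNG(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(side$bounds, pw$bounds)
  expect_identical(side$mode, "pixel-wise")
  # tray transparent, fruit opaque
  expect_true(all(img[, , 4][!cb$fruit] == 0))
  expect_true(all(img[, , 4][cb$fruit] == 1))

  # monotone values map to monotone palette positions
  pal <- grDevices::hcl.colors(256, "YlOrRd", rev = TRUE)
  pal_rgb <- t(grDevices::col2rgb(pal) / 255)
  fruit_idx <- which(cb$fruit)
  v <- pw$values[fruit_idx]
  pos <- vapply(fruit_idx, function(i) {
    px <- c(img[, , 1][i], img[, , 2][i], img[, , 3][i])
    which.min(colSums((t(pal_rgb) - px)^2))
  }, 1L)
  keep <- v >= pw$bounds[1] & v <= pw$bounds[2]   # inside the colour scale
  expect_gt(stats::cor(v[keep], pos[keep], method = "spearman"), 0.99)

  # constant map renders as a single colour
  ow <- objectwise_map(cal, cb$fruit, extract_roi(cal, cb$fruit), fx$bundle)
  p2 <- tempfile(fileext = ".png")
  render_map(ow, p2)
  img2 <- png::readPNG(p2)
  for (ch in 1:3)
    expect_length(unique(img2[, , ch][cb$fruit]), 1)

  empty <- pw
  empty$values[] <- NA_real_
  expect_error(render_map(empty, tempfile(fileext = ".png")), "finite")
})
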