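#' Configuration for the synthetic apple generator
#'
#' Defines the simulated study: per-sample aroma chemical-group contents and
#' the hyperspectral reflectance that encodes them. Each chemical group
#' depresses a smooth fruit-like baseline at its characteristic wavelengths
#' through Gaussian absorption bands whose depth is proportional to the
#' group's content (a Beer-Lambert-like linear link); spectra are then
#' corrupted with multiplicative scatter, an additive baseline offset and
#' white noise — the distortion family that scatter-correcting
#' pre-treatments such as SNV remove.
#'
#' Defaults mirror the apple study conditions: 160 samples, 462 bands over
#' 400-1000 nm, group content ranges of ester 1286.91-15432.56, aldehyde
#' 173.85-12635.05, ketone 13.02-655.99 and alcohol 33.77-1504.67 (ug/kg),
#' and ester/alcohol absorption centres at the reported characteristic
#' wavelengths (ester 413-733 nm, alcohol 519-738 nm, aldehyde anchored at
#' 1000 nm).
#'
#' @param n_samples number of apples.
#' @param n_bands number of spectral bands (default 462).
#' @param wavelength_range nm pair, default `c(400, 1000)`.
#' @param group_specs named list; per group a list with `range` (content
#'   range, ug/kg), `centers` (absorption band centres, nm), `sigma` (band
#'   width, nm) and `strength` (reflectance depletion per unit content).
#' @param scatter_sd log-scale sd of the per-sample lognormal multiplicative
#'   scatter (dimensionless).
#' @param baseline_sd sd of the per-sample additive offset (reflectance units
#'   on the 0-10000 scale).
#' @param noise_sd sd of per-band additive white noise (reflectance units).
#' @param image_size image side length in pixels.
#' @param fruit_radius fruit disk radius in pixels.
#' @param specular_gain relative brightness boost at the fruit centre.
#' @param edge_falloff relative brightness loss at the fruit rim.
#' @param seed integer seed; all generator output is a pure function of the
#'   configuration including this seed.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_samples = 160L,
                             n_bands = 462L,
                             wavelength_range = c(400, 1000),
                             group_specs = default_group_specs(),
                             scatter_sd = 0.10,
                             baseline_sd = 150,
                             noise_sd = 20,
                             image_size = 64L,
                             fruit_radius = 24L,
                             specular_gain = 0.15,
                             edge_falloff = 0.25,
                             seed = 1L) {
  if (n_bands < 2) stop("n_bands must be at least 2")
  if (wavelength_range[1] >= wavelength_range[2])
    stop("wavelength_range must have min < max")
  for (g in names(group_specs)) {
    sp <- group_specs[[g]]
    if (sp$range[1] >= sp$range[2])
      stop("group '", g, "': concentration range must have min < max")
    if (any(sp$centers < wavelength_range[1] | sp$centers > wavelength_range[2]))
      stop("group '", g, "': band centers must lie inside wavelength_range")
    if (sp$sigma <= 0 || sp$strength < 0)
      stop("group '", g, "': sigma must be positive and strength non-negative")
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_bands = as.integer(n_bands),
                 wavelength_range = as.numeric(wavelength_range),
                 group_specs = group_specs,
                 scatter_sd = scatter_sd, baseline_sd = baseline_sd,
                 noise_sd = noise_sd,
                 image_size = as.integer(image_size),
                 fruit_radius = as.integer(fruit_radius),
                 specular_gain = specular_gain, edge_falloff = edge_falloff,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Default chemical-group specifications
#'
#' Content ranges are the study's reported per-group totals (ug/kg). Ester
#' and alcohol absorption centres are the reported characteristic
#' wavelengths; aldehyde and ketone centre lists were not printed in full, so
#' representative sets are used that keep their stated anchors (aldehyde's
#' most informative band at 1000 nm; ketone with bands beyond the visible
#' range). Depletion strengths are scaled so each group's maximal content
#' depresses reflectance by about 1200 units per band on the 0-10000 scale.
#'
#' @param depth peak per-band reflectance depletion at maximal content.
#' @return Named list of group specifications.
#' @export
default_group_specs <- function(depth = 1200) {
  mk <- function(range, centers, sigma = 8) {
    list(range = range, centers = centers, sigma = sigma,
         strength = depth / range[2])
  }
  list(
    ester    = mk(c(1286.91, 15432.56),
                  c(413, 493, 512, 551, 592, 600, 721, 727, 729, 733)),
    aldehyde = mk(c(173.85, 12635.05), c(450, 680, 850, 930, 1000)),
    ketone   = mk(c(13.02, 655.99),    c(430, 530, 640, 760, 820, 980)),
    alcohol  = mk(c(33.77, 1504.67),
                  c(519, 562, 570, 571, 660, 676, 700, 737, 738))
  )
}

# Smooth apple-like reflectance baseline on the 0-10000 scale: low in the
# blue/green, chlorophyll-suppressed through the red, rising to a bright
# NIR plateau.
baseline_reflectance <- function(wl) {
  2000 + 6000 / (1 + exp(-(wl - 650) / 60))
}

# Per-band depletion profile for one group at unit concentration.
group_profile <- function(spec, wl) {
  prof <- numeric(length(wl))
  for (mu in spec$centers)
    prof <- prof + exp(-(wl - mu)^2 / (2 * spec$sigma^2))
  spec$strength * prof
}

#' Generate synthetic mean spectra with known ground truth
#'
#' Draws per-sample group contents uniformly within each group's range and
#' builds reflectance as
#' `r_i(lambda) = m_i * (B(lambda) - sum_g c_ig * k_g * sum_b G(lambda; mu_gb, sigma_g)) + a_i + eps`,
#' with smooth baseline `B`, lognormal scatter `m_i` (unit mean), normal
#' offset `a_i`, and white noise `eps`; the result is clipped to
#' \[0, 10000\]. Output is deterministic for a fixed configuration.
#'
#' @param config a [synthetic_config()].
#' @return List with `matrix` (a [spectrum_matrix()]) and `truth` (a
#'   data.frame of class `ground_truth`: sample id, per-group true content,
#'   the scatter multiplier and baseline offset applied, and an outlier flag,
#'   all `FALSE` until [plant_outliers()] is used).
#' @export
generate_spectra <- function(config) {
  if (!inherits(config, "synthetic_config")) stop("expected a synthetic_config")
  set.seed(config$seed)
  n <- config$n_samples
  wl <- seq(config$wavelength_range[1], config$wavelength_range[2],
            length.out = config$n_bands)
  groups <- names(config$group_specs)
  conc <- sapply(groups, function(g) {
    r <- config$group_specs[[g]]$range
    stats::runif(n, r[1], r[2])
  })
  conc <- matrix(conc, nrow = n, dimnames = list(NULL, groups))
  profiles <- sapply(config$group_specs, group_profile, wl = wl)  # bands x groups
  depletion <- conc %*% t(profiles)                               # samples x bands
  base <- matrix(baseline_reflectance(wl), n, config$n_bands, byrow = TRUE)
  m_i <- stats::rlnorm(n, meanlog = -config$scatter_sd^2 / 2,
                       sdlog = config$scatter_sd)
  a_i <- stats::rnorm(n, 0, config$baseline_sd)
  eps <- matrix(stats::rnorm(n * config$n_bands, 0, config$noise_sd),
                n, config$n_bands)
  r <- m_i * (base - depletion) + a_i + eps
  # a spectrum losing most of its support to the clip bounds carries no signal
  clipped <- rowMeans(r <= 0 | r >= 10000)
  if (any(clipped > 0.5))
    stop("absorption strength too large: reflectance driven to clip bounds")
  r[r < 0] <- 0
  r[r > 10000] <- 10000
  ids <- sprintf("S%03d", seq_len(n))
  truth <- data.frame(sample_id = ids, conc, scatter = m_i, offset = a_i,
                      outlier = FALSE, check.names = FALSE)
  class(truth) <- c("ground_truth", "data.frame")
  list(matrix = spectrum_matrix(r, wl, ids), truth = truth)
}

#' Generate a synthetic hyperspectral cube for one sample
#'
#' Places a disk-shaped fruit on a near-black tray. Each fruit pixel carries
#' the sample's spectrum modulated by a radial brightness profile with a
#' specular boost at the centre and falloff towards the rim; the profile is
#' normalised to unit mean over the disk so the fruit-average spectrum
#' matches the sample's matrix spectrum. Returned as raw sensor counts along
#' with matching dark (near zero) and white (near full-scale) reference
#' frames, so that [calibrate_reflectance()] recovers the reflectance image.
#'
#' @param config a [synthetic_config()].
#' @param truth `ground_truth` from [generate_spectra()].
#' @param sample_id sample to image.
#' @param conc_gradient optional radial concentration gradient: per-pixel
#'   group contents are scaled by `1 + conc_gradient * (r/R - 0.5)`, so a
#'   positive value plants higher content at the rim than at the centre.
#' @return List with `cube` (raw [spectral_cube()]) and `refs`
#'   ([reference_frames()]).
#' @export
generate_cube <- function(config, truth, sample_id, conc_gradient = 0) {
  if (!inherits(config, "synthetic_config")) stop("expected a synthetic_config")
  i <- match(sample_id, truth$sample_id)
  if (is.na(i)) stop("sample_id not present in ground truth: ", sample_id)
  sz <- config$image_size
  R <- config$fruit_radius
  if (2 * R >= sz) stop("fruit_radius exceeds image bounds")
  set.seed(config$seed + 7919L * i)
  wl <- seq(config$wavelength_range[1], config$wavelength_range[2],
            length.out = config$n_bands)
  groups <- names(config$group_specs)
  conc <- as.numeric(truth[i, groups, drop = TRUE])

  cx <- (sz + 1) / 2
  xy <- expand.grid(row = seq_len(sz), col = seq_len(sz))
  rad <- sqrt((xy$row - cx)^2 + (xy$col - cx)^2)
  fruit <- rad <= R
  prof <- 1 + config$specular_gain * exp(-(rad / (0.35 * R))^2) -
    config$edge_falloff * (rad / R)^2
  prof <- prof / mean(prof[fruit])          # unit mean over the disk

  profiles <- sapply(config$group_specs, group_profile, wl = wl)  # bands x groups
  base <- baseline_reflectance(wl)
  # per-pixel reflectance for fruit pixels (pixels x bands)
  scale <- 1 + conc_gradient * (rad[fruit] / R - 0.5)
  conc_px <- outer(scale, conc)                                   # pixels x groups
  refl <- matrix(base, sum(fruit), config$n_bands, byrow = TRUE) -
    conc_px %*% t(profiles)
  refl <- truth$scatter[i] * refl + truth$offset[i]
  refl <- refl * prof[fruit]
  tray_refl <- 120                           # near-black tray

  dark <- 80 + 10 * sin(seq(0, pi, length.out = config$n_bands))
  white <- 9500 * (1 - 0.08 * ((wl - 700) / 300)^2)
  full <- matrix(tray_refl, sz * sz, config$n_bands)
  full[fruit, ] <- refl
  # raw counts: invert the calibration map, plus sensor noise
  D <- matrix(dark, sz * sz, config$n_bands, byrow = TRUE)
  W <- matrix(white, sz * sz, config$n_bands, byrow = TRUE)
  raw <- D + pmax(full, 0) / 10000 * (W - D) +
    matrix(stats::rnorm(sz * sz * config$n_bands, 0, config$noise_sd / 10),
           sz * sz, config$n_bands)
  cube <- spectral_cube(array(raw, dim = c(sz, sz, config$n_bands)), wl,
                        calibrated = FALSE,
                        metadata = list(sample_id = sample_id))
  refs <- reference_frames(
    dark = array(D, dim = c(sz, sz, config$n_bands)),
    white = array(W, dim = c(sz, sz, config$n_bands)))
  list(cube = cube, refs = refs, fruit = matrix(fruit, sz, sz))
}

#' Plant label outliers
#'
#' Re-draws the concentration labels of a random subset of samples
#' independently of their spectra, marking them in the outlier flag. These
#' are the anomalous samples that Monte-Carlo cross-validation screening is
#' expected to find: their spectra no longer match their labels.
#'
#' @param truth `ground_truth` from [generate_spectra()].
#' @param matrix the matching [spectrum_matrix()] (returned unchanged; kept
#'   in the signature so the pairing is explicit).
#' @param fraction fraction of samples to corrupt, in `[0, 0.5)`.
#' @param seed integer seed.
#' @param config the [synthetic_config()] supplying the ranges to re-draw
#'   from.
#' @return List with `matrix` (unchanged) and `truth` (labels re-drawn,
#'   flags set on exactly `round(fraction * n)` samples).
#' @export
plant_outliers <- function(truth, matrix, fraction, seed,
                           config = synthetic_config()) {
  if (fraction < 0 || fraction >= 0.5) stop("fraction must lie in [0, 0.5)")
  if (fraction == 0) return(list(matrix = matrix, truth = truth))
  set.seed(seed)
  n <- nrow(truth)
  k <- round(fraction * n)
  pick <- sample.int(n, k)
  for (g in names(config$group_specs)) {
    r <- config$group_specs[[g]]$range
    truth[[g]][pick] <- stats::runif(k, r[1], r[2])
  }
  truth$outlier <- FALSE
  truth$outlier[pick] <- TRUE
  list(matrix = matrix, truth = truth)
}

#' Ground truth as a compound table
#'
#' Expands per-sample group totals into a GC-MS-style compound table: each
#' group's total is split across a few synthetic member compounds with fixed
#' proportions, and an internal-standard row is added per sample so the
#' relative-quantification path is exercised end to end.
#'
#' @param truth `ground_truth` from [generate_spectra()].
#' @param is_spec an [internal_standard()] (defaults supply 3-nonanone).
#' @param compounds_per_group number of member compounds per group.
#' @return A `data.frame` compound table with columns `sample_id`,
#'   `compound`, `class`, `area` (peak area such that quantification
#'   reproduces the true totals).
#' @export
truth_to_compound_table <- function(truth, is_spec = internal_standard(),
                                    compounds_per_group = 3L) {
  groups <- setdiff(names(truth), c("sample_id", "scatter", "offset", "outlier"))
  # fixed split proportions per group (sum to 1)
  w <- seq_len(compounds_per_group)
  w <- w / sum(w)
  area_is <- 1e6
  conv <- is_spec$amount_ug / is_spec$sample_mass_g * 1000  # ug/kg at area ratio 1
  rows <- list()
  for (g in groups) {
    for (j in seq_len(compounds_per_group)) {
      conc <- truth[[g]] * w[j]
      rows[[paste(g, j)]] <- data.frame(
        sample_id = truth$sample_id,
        compound = sprintf("synthetic %s %d", g, j),
        class = g,
        area = conc / conv * area_is)
    }
  }
  rows[["IS"]] <- data.frame(sample_id = truth$sample_id,
                             compound = is_spec$name,
                             class = "other",
                             area = area_is)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(match(out$sample_id, truth$sample_id)), , drop = FALSE]
}
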