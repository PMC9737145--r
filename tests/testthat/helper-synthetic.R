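# Small-scale generator configs shared across test files. Reduced sample,
# band and image counts keep unit tests fast; the acceptance tests use the
# full default configuration.

tiny_config <- function(seed = 1L, ...) {
  synthetic_config(n_samples = 40L, n_bands = 80L, image_size = 32L,
                   fruit_radius = 12L, seed = seed, ...)
}

# A one-group configuration with no stochastic corruption: reflectance is a
# deterministic function of the single concentration.
clean_one_group <- function(seed = 1L, n = 20L) {
  synthetic_config(
    n_samples = n, n_bands = 80L, seed = seed,
    group_specs = list(ester = list(range = c(1000, 15000),
                                    centers = c(550, 720), sigma = 10,
                                    strength = 1200 / 15000)),
    scatter_sd = 0, baseline_sd = 0, noise_sd = 0)
}

group_names <- c("ester", "aldehyde", "ketone", "alcohol")

truth_matrix <- function(truth) as.matrix(truth[, group_names])
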