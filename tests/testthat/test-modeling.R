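test_that("the 3:2 split is exhaustive, disjoint and reproducible", {
  ids <- sprintf("S%03d", 1:160)
  sp <- split_samples(ids, seed = 3)
  expect_length(sp$calibration, 96)
  expect_length(sp$validation, 64)
  expect_setequal(c(sp$calibration, sp$validation), ids)
  expect_length(intersect(sp$calibration, sp$validation), 0)
  sp2 <- split_samples(ids, seed = 3)
  expect_identical(sp, sp2)
  expect_error(split_samples(ids[1:3]), "at least 5")
})

test_that("MCCV inclusion counts honour the subsample contract", {
  set.seed(1)
  m <- spectrum_matrix(matrix(rnorm(10 * 6), 10, 6),
                       seq(400, 900, length.out = 6))
  scr <- mccv_screen(m, rnorm(10), n_cycles = 1, fraction = 0.8, seed = 2)
  expect_identical(sort(unique(scr$inclusion_count)), c(0L, 1L))
  expect_identical(sum(scr$inclusion_count == 1L), 8L)
  expect_identical(sum(scr$inclusion_count == 0L), 2L)
  expect_identical(sum(scr$inclusion_count), 8L)
  expect_error(mccv_screen(m, rnorm(10), n_cycles = 0), "n_cycles")
  expect_error(mccv_screen(m, rnorm(10), fraction = 1), "fraction")
})

test_that("clean data is mostly unflagged at the default threshold", {
  cfg <- tiny_config(seed = 23)
  gen <- generate_spectra(cfg)
  scr <- mccv_screen(snv(gen$matrix), gen$truth$ester, n_cycles = 60, seed = 5)
  expect_lte(mean(scr$outlier), 0.05)
})

test_that("a planted informative band earns the top importance", {
  set.seed(7)
  n <- 60; p <- 30
  X <- matrix(rnorm(n * p), n, p)
  y <- 3 * X[, 17] + rnorm(n, 0, 0.1)
  m <- spectrum_matrix(X, seq(400, 980, length.out = p))
  sel <- grid_search_select(m, y, model_grid(num_trees = 100, max_depth = 0,
                                             k = 3),
                            k_folds = 5, seed = 8)
  expect_identical(unname(which.max(sel$importance)), 17L)
  expect_true(17L %in% sel$wavelength_idx)
})

test_that("an uninformative spectrum yields no apparent CV skill", {
  r2 <- replicate(10, {
    s <- sample.int(1e6, 1)
    set.seed(s)
    n <- 40; p <- 20
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    m <- spectrum_matrix(X, seq(400, 980, length.out = p))
    sel <- grid_search_select(m, y, model_grid(num_trees = 50, max_depth = 0,
                                               k = 5),
                              k_folds = 10, seed = s)
    1 - min(sel$cv_rmse)^2 / mean((y - mean(y))^2)
  })
  expect_lte(mean(r2), 0.1)
})

test_that("a singleton grid is returned as-is and bad k is rejected", {
  set.seed(9)
  m <- spectrum_matrix(matrix(rnorm(30 * 12), 30, 12),
                       seq(400, 950, length.out = 12))
  y <- rnorm(30)
  sel <- grid_search_select(m, y, model_grid(num_trees = 70, max_depth = 4,
                                             mtry = 3, k = 6),
                            k_folds = 5, seed = 10)
  expect_identical(sel$num_trees, 70)
  expect_identical(sel$max_depth, 4)
  expect_identical(sel$mtry, 3)
  expect_identical(sel$k, 6)
  expect_length(sel$wavelength_idx, 6)
  expect_error(
    grid_search_select(m, y, model_grid(k = 20), k_folds = 5, seed = 1),
    "exceeds")
})

test_that("separated top-k picking spreads over importance peaks", {
  imp <- c(0.5, 0.45, 0.4, 0.02, 0.3, 0.28, 0.01, 0.2)
  wl <- c(400, 401, 402, 450, 500, 501, 550, 600)
  # greedy order: 400 accepted; 401/402 within 5 nm skipped; 500 accepted;
  # 501 skipped; 600 accepted; 450 fills the fourth slot
  got <- aromahsi:::pick_top_separated(imp, wl, 4, min_sep = 5)
  expect_identical(got, c(1L, 4L, 5L, 8L))
  # with no separation it is the plain top-k
  plain <- aromahsi:::pick_top_separated(imp, wl, 4, min_sep = 0)
  expect_identical(plain, sort(order(-imp)[1:4]))
})

test_that("forest fit and prediction are deterministic and serializable", {
  set.seed(11)
  n <- 50; p <- 15
  wl <- seq(400, 960, length.out = p)
  X <- matrix(rnorm(n * p), n, p)
  y <- 2 * X[, 4] - X[, 9]
  m <- spectrum_matrix(X, wl)

  const <- fit_rf_model(m, rep(5, n), manual_selection(m, num_trees = 50),
                        seed = 12)
  expect_true(all(predict(const, m) == 5))

  deep <- manual_selection(m, num_trees = 400, mtry = p)
  b <- fit_rf_model(m, y, deep, seed = 13, target = "toy")
  expect_gte(r_squared(y, predict(b, m)), 0.95)  # deep fit memorizes training

  b2 <- fit_rf_model(m, y, deep, seed = 13)
  expect_identical(predict(b, m), predict(b2, m))

  dir <- tempfile()
  save_bundle(b, dir)
  b3 <- load_bundle(dir)
  expect_identical(predict(b3, m), predict(b, m))
  expect_identical(b3$wavelength_idx, b$wavelength_idx)
  expect_identical(b3$provenance, b$provenance)

  wrong <- spectrum_matrix(X, wl + 5)
  expect_error(predict(b, wrong), "grid")
})

test_that("selected wavelengths track the all-wavelength model closely", {
  cfg <- synthetic_config(seed = 41, scatter_sd = 0, baseline_sd = 0,
                          noise_sd = 0)
  gen <- generate_spectra(cfg)
  sp <- split_samples(gen$matrix$sample_ids, seed = 41)
  m <- snv(gen$matrix)
  y <- stats::setNames(gen$truth$alcohol, gen$truth$sample_id)
  Xc <- aromahsi:::sm_subset(m, sp$calibration)
  sel <- grid_search_select(Xc, y[sp$calibration],
                            model_grid(num_trees = 300, max_depth = 0,
                                       k = c(10, 15)),
                            seed = 41)
  b_sel <- fit_rf_model(Xc, y[sp$calibration], sel, seed = 41, "alcohol")
  b_all <- fit_rf_model(Xc, y[sp$calibration], manual_selection(Xc),
                        seed = 41, "alcohol")
  r_sel <- evaluate_model(b_sel, sp, m, y)$Rv2
  r_all <- evaluate_model(b_all, sp, m, y)$Rv2
  expect_gte(r_sel, r_all - 0.05)
})
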