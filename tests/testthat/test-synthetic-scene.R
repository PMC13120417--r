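test_that("wavelength grid is uniform with the documented spacing", {
  g <- make_wavelength_grid(171, 1000, 1700)
  expect_length(g$values, 171)
  expect_equal(g$values[1], 1000)
  expect_equal(g$values[171], 1700)
  expect_equal(g$spacing, 700 / 170)
  expect_equal(round(g$spacing, 1), 4.1)
  d <- diff(g$values)
  expect_lt(max(abs(d - mean(d))) / mean(d), 1e-9)

  expect_equal(make_wavelength_grid(2, 1000, 1700)$values, c(1000, 1700))
  expect_equal(make_wavelength_grid(8, 0, 7)$values, 0:7)
  expect_error(make_wavelength_grid(1, 0, 1), class = "sstfpo_invalid_argument")
  expect_error(make_wavelength_grid(5, 10, 10), class = "sstfpo_invalid_argument")
})

test_that("class spectra follow the continuum-plus-dips model", {
  grid <- make_wavelength_grid(50, 1000, 1700)
  # degenerate entry: flat continuum, no dips, no variability
  lib <- spectral_library(
    list(flat = list(level = 50, slope = 0, features = feat(),
                     variability = 0),
         dip = list(level = 60, slope = 0,
                    features = feat(1350, 40, 20), variability = 0)),
    background = list(level = 10, slope = 0, features = feat(),
                      variability = 0))
  expect_equal(sample_class_spectrum(lib, 1L, grid, seed = 1),
               rep(50, 50))
  # the single dip pulls the minimum to the band nearest its center
  s <- sample_class_spectrum(lib, 2L, grid, seed = 1)
  expect_equal(which.min(s), which.min(abs(grid$values - 1350)))
  expect_error(sample_class_spectrum(lib, 99L, grid), class = "sstfpo_key_error")
})

test_that("spectrum draws are seed-deterministic and bounded", {
  grid <- make_wavelength_grid(40, 1000, 1700)
  lib <- default_spectral_library()
  s1 <- sample_class_spectrum(lib, 3L, grid, seed = 11)
  s2 <- sample_class_spectrum(lib, 3L, grid, seed = 11)
  s3 <- sample_class_spectrum(lib, 3L, grid, seed = 12)
  expect_identical(s1, s2)
  expect_false(identical(s1, s3))
  for (k in 0:13) {
    s <- sample_class_spectrum(lib, k, grid, seed = k + 1)
    expect_true(all(s >= 0 & s <= 100))
  }
})

test_that("default library keeps the 13 target classes separable", {
  grid <- make_wavelength_grid(171, 1000, 1700)
  expect_gt(library_separability(default_spectral_library(), grid), 25)
})

test_that("rendered scenes label region interiors after margin erosion", {
  sc0 <- render_small(small_scene_spec(margin = 0L))
  counts0 <- table(factor(sc0$mask$values[sc0$mask$values > 0], levels = 1:13))
  expect_true(all(counts0 == 25))          # one 5x5 region per class

  sc1 <- render_small(small_scene_spec(margin = 1L))
  counts1 <- table(factor(sc1$mask$values[sc1$mask$values > 0], levels = 1:13))
  expect_true(all(counts1 == 9))           # (5 - 2)^2 interior pixels

  # no labeled pixel sits within the margin of a different material
  m <- sc1$mask$values; cmap <- sc1$class_map
  lab <- which(m > 0, arr.ind = TRUE)
  for (i in seq_len(nrow(lab))) {
    r <- lab[i, 1]; cc <- lab[i, 2]
    nb <- cmap[max(1, r - 1):min(nrow(cmap), r + 1),
               max(1, cc - 1):min(ncol(cmap), cc + 1)]
    expect_true(all(nb == m[r, cc]))
  }
})

test_that("rendering is a pure function of the scene spec", {
  a <- render_small(small_scene_spec(seed = 31))
  b <- render_small(small_scene_spec(seed = 31))
  expect_identical(a$raw$data, b$raw$data)
  expect_identical(a$mask$values, b$mask$values)
  expect_identical(a$white, b$white)
  expect_identical(a$dark, b$dark)
  c <- render_small(small_scene_spec(seed = 32))
  expect_false(identical(a$raw$data, c$raw$data))
})

test_that("region placement failures raise a configuration error", {
  bad <- scene_spec(height = 40L, width = 40L, n_bands = 10L,
                    n_regions_per_class = 10L, region_size = 7L,
                    fillet = c(5L, 5L, 36L, 36L), seed = 1L)
  expect_error(render_scene(bad), class = "sstfpo_configuration_error")
})

test_that("calibration inverts the DN synthesis model", {
  # noise-free render: calibration recovers the intended reflectance exactly
  sc <- render_small(small_scene_spec(noise_sd = 0))
  cal <- calibrate_reflectance(sc$raw, sc$white, sc$dark)
  expect_equal(cal$n_guarded, 0)
  expect_lt(max(abs(cal$cube$data - sc$truth$data)), 1e-9)

  # noisy render: per-element deviations behave like the injected noise
  scn <- render_small(small_scene_spec(noise_sd = 1.5))
  caln <- calibrate_reflectance(scn$raw, scn$white, scn$dark)
  dev <- caln$cube$data - scn$truth$data
  expect_gt(mean(abs(dev) <= 3 * 1.5), 0.995)
  expect_lt(sd(dev), 1.5 * 1.05)
})
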