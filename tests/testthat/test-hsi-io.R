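make_cube <- function(h, w, b, lo = 1000, hi = 1700, domain = "dn",
                      fill = NULL) {
  vals <- if (is.null(fill)) array(seq_len(h * w * b), c(h, w, b))
          else array(fill, c(h, w, b))
  hsi_cube(vals, seq(lo, hi, length.out = b), domain)
}

test_that("reflectance calibration anchors and affinity hold", {
  raw <- make_cube(2, 2, 3, fill = 50)
  white <- array(90, c(2, 2, 3)); dark <- array(10, c(2, 2, 3))
  cal <- calibrate_reflectance(raw, white, dark)
  expect_true(all(cal$cube$data == 50))
  expect_equal(cal$cube$domain, "reflectance")
  expect_equal(cal$n_guarded, 0)

  expect_true(all(calibrate_reflectance(make_cube(2, 2, 3, fill = 10),
                                        white, dark)$cube$data == 0))
  expect_true(all(calibrate_reflectance(make_cube(2, 2, 3, fill = 90),
                                        white, dark)$cube$data == 100))

  # affine per element: scaling the span halves the output
  cal2 <- calibrate_reflectance(raw, dark + 2 * (white - dark), dark)
  expect_equal(cal2$cube$data, cal$cube$data / 2)
})

test_that("calibration guards degenerate denominators and checks shapes", {
  raw <- make_cube(2, 2, 2, fill = 5)
  white <- array(10, c(2, 2, 2)); dark <- array(1, c(2, 2, 2))
  white[1, 1, 1] <- dark[1, 1, 1]          # zero span at one element
  cal <- calibrate_reflectance(raw, white, dark)
  expect_equal(cal$n_guarded, 1)
  expect_equal(cal$cube$data[1, 1, 1], 0)
  expect_true(all(is.finite(cal$cube$data)))

  expect_error(calibrate_reflectance(raw, array(1, c(3, 2, 2)), dark),
               class = "sstfpo_invalid_argument")
  refl <- make_cube(2, 2, 2, domain = "reflectance", fill = 1)
  expect_error(calibrate_reflectance(refl, white, dark),
               class = "sstfpo_invalid_argument")
})

test_that("band subsetting keeps the closed interval and is idempotent", {
  # a uniform 268-band grid over 600-1700 nm holds 170 points in
  # [1000, 1700] (frozen by enumerating the constructed grid)
  cube <- make_cube(2, 2, 268, lo = 600, hi = 1700)
  sub <- subset_bands(cube, 1000, 1700)
  lam <- seq(600, 1700, length.out = 268)
  expect_equal(dim(sub$data)[3], sum(lam >= 1000 & lam <= 1700))
  expect_equal(dim(sub$data)[3], 170)
  expect_true(all(sub$wavelengths$values >= 1000 &
                    sub$wavelengths$values <= 1700))

  again <- subset_bands(sub, 1000, 1700)
  expect_identical(again$data, sub$data)

  full <- subset_bands(cube, 600, 1700)
  expect_identical(full$data, cube$data)

  expect_error(subset_bands(cube, 2000, 2100),
               class = "sstfpo_invalid_argument")
})

test_that("ENVI float32 cubes round-trip across interleaves", {
  set.seed(9)
  cube <- hsi_cube(array(runif(4 * 5 * 6, 0, 100), c(4, 5, 6)),
                   seq(1000, 1700, length.out = 6), "reflectance")
  p_bsq <- file.path(tempdir(), "cube_bsq")
  p_bil <- file.path(tempdir(), "cube_bil")
  write_envi(cube, p_bsq, interleave = "bsq")
  write_envi(cube, p_bil, interleave = "bil")
  r_bsq <- read_envi(p_bsq)
  r_bil <- read_envi(p_bil)
  # float32 storage: read-back equals input at single precision, and the
  # two interleaves decode to identical arrays
  expect_equal(r_bsq$data, cube$data, tolerance = 1e-6)
  expect_identical(r_bsq$data, r_bil$data)
  expect_equal(r_bsq$wavelengths$values, cube$wavelengths$values)
  expect_equal(r_bsq$domain, "reflectance")
  # a second write/read of the read-back is bit-exact
  write_envi(r_bsq, p_bsq)
  expect_identical(read_envi(p_bsq)$data, r_bsq$data)
})

test_that("ENVI readers reject inconsistent or unsupported files", {
  cube <- make_cube(3, 3, 4, fill = 1)
  p <- file.path(tempdir(), "bad_cube")
  write_envi(cube, p)
  # truncate the binary: header says more data than the file holds
  writeBin(raw(10), p)
  expect_error(read_envi(p), class = "sstfpo_format_error")
  # unsupported interleave
  write_envi(cube, p)
  hdr <- readLines(paste0(p, ".hdr"))
  writeLines(sub("interleave = bsq", "interleave = bip", hdr),
             paste0(p, ".hdr"))
  expect_error(read_envi(p), class = "sstfpo_format_error")
  expect_error(read_envi(file.path(tempdir(), "no_such_cube")),
               class = "sstfpo_format_error")
})

test_that("label masks round-trip and validate their range", {
  m <- label_mask(matrix(c(0L, 1L, 13L, 0L, 0L, 13L, 1L, 0L, 0L), 3, 3),
                  n_classes = 13L)
  p <- file.path(tempdir(), "mask_rt")
  write_label_mask(m, p)
  back <- read_label_mask(p)
  expect_identical(back$values, m$values)
  expect_equal(back$n_classes, 13L)

  expect_error(label_mask(matrix(14L, 2, 2), n_classes = 13L),
               class = "sstfpo_format_error")
  z <- label_mask(matrix(0L, 3, 3))
  write_label_mask(z, p)
  expect_identical(read_label_mask(p)$values, z$values)
  expect_equal(nrow(enumerate_target_pixels(z)), 0L)
})
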