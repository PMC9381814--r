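make_cube <- function(rows = 6, cols = 5, wl = seq(400, 1000, length.out = 12),
                      seed = 3) {
  set.seed(seed)
  hyperspectral_cube(array(runif(rows * cols * length(wl)),
                           c(rows, cols, length(wl))), wl)
}

test_that("ENVI round trip is lossless for all three interleaves", {
  cube <- make_cube()
  for (il in c("bsq", "bil", "bip")) {
    hdr <- file.path(tempdir(), paste0("cube_", il, ".hdr"))
    write_envi_cube(cube, hdr, interleave = il)
    back <- read_envi_cube(hdr)
    expect_identical(back$reflectance, cube$reflectance)
    expect_equal(back$wavelengths, cube$wavelengths)
  }
  # float32 storage round-trips within single precision
  hdr <- file.path(tempdir(), "cube_f32.hdr")
  write_envi_cube(cube, hdr, interleave = "bil", data_type = 4)
  back <- read_envi_cube(hdr)
  expect_equal(back$reflectance, cube$reflectance, tolerance = 1e-6)
})

test_that("ENVI headers without wavelengths or with bad shapes error", {
  cube <- make_cube()
  hdr <- file.path(tempdir(), "broken.hdr")
  write_envi_cube(cube, hdr)
  lines <- readLines(hdr)
  writeLines(lines[!grepl("^wavelength =", lines)], hdr)
  expect_error(read_envi_cube(hdr), "wavelength")
  # truncate the binary: shape mismatch
  write_envi_cube(cube, hdr)
  bin <- sub("\\.hdr$", "", hdr)
  writeBin(raw(10), bin)
  expect_error(read_envi_cube(hdr), "shape")
})

test_that("generator cubes keep their shape through ENVI", {
  wl <- seq(400, 1000, length.out = 300)
  cb <- generate_cube(baseline_spectrum(wl), wl, shape = c(32, 32), seed = 1)
  hdr <- file.path(tempdir(), "gen.hdr")
  write_envi_cube(cb$cube, hdr, interleave = "bip")
  back <- read_envi_cube(hdr)
  expect_equal(dim(back$reflectance), c(32L, 32L, 300L))
  expect_identical(back$reflectance, cb$cube$reflectance)
})

test_that("NDVI arithmetic, nearest-band lookup and edge cases", {
  wl <- c(660, 780)
  refl <- array(0, c(1, 3, 2))
  refl[1, 1, ] <- c(0.3, 0.3)   # symmetric -> 0
  refl[1, 2, ] <- c(0.1, 0.5)   # (0.5-0.1)/0.6
  refl[1, 3, ] <- c(0.5, 0.1)   # sign flip
  cube <- hyperspectral_cube(refl, wl)
  nd <- ndvi_map(cube)
  expect_equal(nd$values[1, 1], 0)
  expect_equal(nd$values[1, 2], 0.4 / 0.6, tolerance = 1e-12)
  expect_equal(nd$values[1, 3], -0.4 / 0.6, tolerance = 1e-12)
  expect_equal(nd$nir_band_index, 2)
  expect_equal(nd$red_band_index, 1)
  # zero denominator pixels are defined as background (0)
  dark <- hyperspectral_cube(array(0, c(2, 2, 2)), wl)
  expect_true(all(ndvi_map(dark)$values == 0))
  # NDVI bounded for nonnegative reflectance
  cube2 <- make_cube()
  nd2 <- ndvi_map(cube2)
  expect_true(all(nd2$values >= -1 & nd2$values <= 1))
  # single-band cube cannot form an NDVI
  one <- hyperspectral_cube(array(0.5, c(2, 2, 1)), 700)
  expect_error(ndvi_map(one), "bands")
})

test_that("segmentation is strict, monotone in threshold, and exact on
           noise-free cubes", {
  wl <- seq(400, 1000, length.out = 25)
  cb <- generate_cube(baseline_spectrum(wl), wl, shape = c(14, 14), seed = 2,
                      pixel_noise_sd = 0)
  nd <- ndvi_map(cb$cube)
  mask <- segment_leaf(nd)
  expect_identical(mask$keep, cb$leaf_mask)
  expect_equal(mask$n_pixels, sum(cb$leaf_mask))
  # monotone: raising the threshold never adds pixels
  t_grid <- c(-0.5, 0, 0.2, 0.5, 1)
  sizes <- vapply(t_grid, function(t) segment_leaf(nd, t)$n_pixels, numeric(1))
  expect_true(all(diff(sizes) <= 0))
  # NDVI <= 1 always, so threshold 1 keeps nothing
  expect_equal(segment_leaf(nd, 1)$n_pixels, 0)
  # an all-background cube segments to the empty mask
  bg <- array(rep(seq(0.4, 0.1, length.out = 25), each = 64), c(8, 8, 25))
  expect_equal(segment_leaf(ndvi_map(hyperspectral_cube(bg, wl)))$n_pixels, 0)
})

test_that("mean-spectrum extraction is the masked arithmetic mean", {
  wl <- seq(500, 900, length.out = 10)
  s <- seq(0.1, 0.5, length.out = 10)
  uni <- hyperspectral_cube(array(rep(s, each = 12), c(3, 4, 10)), wl)
  full <- matrix(TRUE, 3, 4)
  expect_equal(extract_mean_spectrum(uni, full), s, tolerance = 1e-14)
  # two-pixel mask: (a + b) / 2
  cube <- make_cube(3, 4, wl)
  m2 <- matrix(FALSE, 3, 4); m2[1, 1] <- TRUE; m2[2, 3] <- TRUE
  expect_equal(extract_mean_spectrum(cube, m2),
               (cube$reflectance[1, 1, ] + cube$reflectance[2, 3, ]) / 2,
               tolerance = 1e-14)
  # linearity across disjoint masks
  ma <- matrix(FALSE, 3, 4); ma[1, ] <- TRUE
  mb <- matrix(FALSE, 3, 4); mb[3, ] <- TRUE
  both <- ma | mb
  lhs <- extract_mean_spectrum(cube, both)
  rhs <- (sum(ma) * extract_mean_spectrum(cube, ma) +
          sum(mb) * extract_mean_spectrum(cube, mb)) / sum(both)
  expect_equal(lhs, rhs, tolerance = 1e-12)
  # empty segmentation signals a failed acquisition
  expect_error(extract_mean_spectrum(cube, matrix(FALSE, 3, 4)), "empty")
})
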