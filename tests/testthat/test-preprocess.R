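make_refs <- function(rows, cols, nb, white = 9, dark = 1) {
  wl <- seq(450, 950, length.out = nb)
  ref_frames(hs_cube(array(white, c(rows, cols, nb)), wl),
             hs_cube(array(dark, c(rows, cols, nb)), wl))
}

test_that("radiometric calibration implements (RI - DI) / (WI - DI)", {
  refs <- make_refs(2, 2, 4)
  wl <- refs$white$wavelengths_nm

  # RI = WI -> all ones; RI = DI -> all zeros
  ci1 <- calibrate(hs_cube(array(9, c(2, 2, 4)), wl), refs)
  expect_true(all(ci1$values == 1))
  expect_identical(ci1$state, "calibrated")
  ci0 <- calibrate(hs_cube(array(1, c(2, 2, 4)), wl), refs)
  expect_true(all(ci0$values == 0))

  # hand case: RI = 5, DI = 1, WI = 9 -> (5-1)/(9-1) = 0.5
  ci <- calibrate(hs_cube(array(5, c(2, 2, 4)), wl), refs)
  expect_true(all(ci$values == 0.5))

  expect_error(
    calibrate(hs_cube(array(5, c(3, 2, 4)), wl), refs),
    class = "hsderm_contract_error")
})

test_that("dead voxels (WI = DI) give 0 and are counted, negatives clamp", {
  wl <- seq(450, 950, length.out = 3)
  white <- array(9, c(2, 2, 3)); white[1, 1, 2] <- 1
  refs <- ref_frames(hs_cube(white, wl), hs_cube(array(1, c(2, 2, 3)), wl))
  raw <- array(5, c(2, 2, 3)); raw[2, 2, 1] <- 0  # below dark
  ci <- calibrate(hs_cube(raw, wl), refs)
  expect_identical(attr(ci, "n_dead_voxels"), 1L)
  expect_identical(ci$values[1, 1, 2], 0)
  expect_identical(ci$values[2, 2, 1], 0)  # clamped
  ci2 <- calibrate(hs_cube(raw, wl), refs,
                   preprocess_config(clamp_negative = FALSE))
  expect_lt(ci2$values[2, 2, 1], 0)
})

test_that("band trimming removes the low-response edge bands", {
  sc <- make_scene(scene_config(seed = 31))
  trimmed <- trim_bands(calibrate(sc$raw, sc$refs))
  expect_identical(dim(trimmed$values)[3], 116L)
  expect_equal(trimmed$wavelengths_nm,
               sc$raw$wavelengths_nm[5:120])

  cube <- flat_cube(1:12 / 12)
  expect_identical(trim_bands(cube, preprocess_config(0, 0))$values,
                   cube$values)
  expect_error(trim_bands(flat_cube(1:9 / 9), preprocess_config()),
               class = "hsderm_contract_error")
})

test_that("spectral smoothing is a truncated centered moving average", {
  # hand case: [0,0,1,0,0] window 3 -> [0, 1/3, 1/3, 1/3, 0]
  cube <- flat_cube(c(0, 0, 1, 0, 0))
  sm <- smooth_spectra(cube, preprocess_config(smooth_window = 3))
  expect_equal(sm$values[1, 1, ], c(0, 1 / 3, 1 / 3, 1 / 3, 0))

  # constant spectrum unchanged; window 1 is the identity
  const <- flat_cube(rep(0.4, 7))
  expect_equal(smooth_spectra(const, preprocess_config(smooth_window = 5)),
               const)
  expect_identical(smooth_spectra(cube, preprocess_config(smooth_window = 1)),
                   cube)
  expect_error(preprocess_config(smooth_window = 4),
               class = "hsderm_contract_error")
})

test_that("smoothing never widens the per-spectrum value range", {
  withr::with_seed(5, {
    for (i in 1:20) {
      s <- runif(15)
      sm <- smooth_spectra(flat_cube(s),
                           preprocess_config(smooth_window = 5))$values[1, 1, ]
      expect_gte(min(sm), min(s))
      expect_lte(max(sm), max(s))
    }
  })
})

test_that("min-max normalization maps each signature to [0, 1]", {
  cube <- tiny_cube(list(c(2, 4, 6), c(0, 0.5, 1), c(3, 3, 3)), 1, 3,
                    state = "calibrated")
  nm <- normalize_minmax(cube)
  expect_equal(nm$values[1, 1, ], c(0, 0.5, 1))
  expect_equal(nm$values[1, 2, ], c(0, 0.5, 1))  # already [0,1]: fixed point
  expect_equal(nm$values[1, 3, ], c(0, 0, 0))    # flat spectrum rule
  expect_identical(nm$state, "preprocessed")
})

test_that("normalization is idempotent and affine-invariant", {
  withr::with_seed(8, {
    for (i in 1:20) {
      s <- rnorm(10)
      a <- runif(1, 0.1, 5); b <- rnorm(1)
      n1 <- normalize_minmax(flat_cube(s, 1, 1))$values[1, 1, ]
      n2 <- normalize_minmax(flat_cube(a * s + b, 1, 1))$values[1, 1, ]
      n3 <- normalize_minmax(flat_cube(n1, 1, 1))$values[1, 1, ]
      expect_equal(n2, n1, tolerance = 1e-12)
      expect_equal(n3, n1, tolerance = 1e-12)
    }
  })
})

test_that("the chain composes calibration, trim, smooth, normalize in order", {
  sc <- make_scene(scene_config(seed = 33))
  pre <- preprocess_chain(sc$raw, sc$refs)
  expect_identical(dim(pre$values)[3], 116L)
  expect_identical(pre$state, "preprocessed")
  expect_true(all(pre$values >= 0 & pre$values <= 1))

  # manual composition agrees
  cfg <- preprocess_config()
  manual <- normalize_minmax(smooth_spectra(trim_bands(
    calibrate(sc$raw, sc$refs, cfg), cfg), cfg))
  expect_equal(pre$values, manual$values)

  # normalization off: state stays calibrated, values can exceed 1
  pre2 <- preprocess_chain(sc$raw, sc$refs,
                           preprocess_config(normalize = FALSE))
  expect_identical(pre2$state, "calibrated")
})
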