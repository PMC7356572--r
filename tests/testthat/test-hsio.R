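test_that("ENVI cube write/read round-trips bitwise, preserving state", {
  sc <- make_scene(scene_config(seed = 21))
  for (cube in list(sc$raw, preprocess_chain(sc$raw, sc$refs))) {
    # float32 storage: round-trip through single precision first
    path <- withr::local_tempfile(fileext = ".hdr")
    write_cube(cube, path)
    back <- read_cube(path)
    f32 <- read_cube(write_cube(back, withr::local_tempfile(fileext = ".hdr")))
    expect_identical(back$values, f32$values)  # bitwise after f32 quantization
    expect_equal(back$wavelengths_nm, cube$wavelengths_nm)
    expect_identical(back$state, cube$state)
    expect_equal(back$values, cube$values, tolerance = 1e-6)
  }
})

test_that("written ENVI pair has standard header fields and exact byte size", {
  cube <- flat_cube(c(0.1, 0.5, 0.9), rows = 4, cols = 6)
  path <- withr::local_tempfile(fileext = ".hdr")
  write_cube(cube, path)
  hdr <- readLines(path)
  expect_true(any(grepl("^samples = 6$", hdr)))
  expect_true(any(grepl("^lines = 4$", hdr)))
  expect_true(any(grepl("^bands = 3$", hdr)))
  expect_true(any(grepl("^interleave = bsq$", hdr)))
  expect_true(any(grepl("^data type = 4$", hdr)))
  bin <- sub("\\.hdr$", ".raw", path)
  expect_identical(file.size(bin), 4 * 6 * 3 * 4)  # rows*cols*bands*4 bytes
})

test_that("trimmed cube writes its band count into the header", {
  sc <- make_scene(scene_config(seed = 22))
  pre <- preprocess_chain(sc$raw, sc$refs)
  path <- withr::local_tempfile(fileext = ".hdr")
  write_cube(pre, path)
  expect_true(any(grepl("^bands = 116$", readLines(path))))
})

test_that("cube reading validates header contents", {
  cube <- flat_cube(c(1, 2, 3))
  path <- withr::local_tempfile(fileext = ".hdr")
  write_cube(cube, path)
  # drop the wavelength list -> format error
  hdr <- readLines(path)
  writeLines(hdr[!grepl("^wavelength =", hdr)], path)
  expect_error(read_cube(path), class = "hsderm_format_error")
  expect_error(read_cube(withr::local_tempfile(fileext = ".hdr")),
               class = "hsderm_io_error")
})

test_that("mask PNG round-trips with 0/nonzero semantics", {
  mask <- matrix(FALSE, 5, 7); mask[2, 3] <- TRUE; mask[5, 7] <- TRUE
  path <- withr::local_tempfile(fileext = ".png")
  write_mask(mask, path)
  expect_identical(read_mask(path), mask)

  # all-zero PNG -> no positives
  p0 <- withr::local_tempfile(fileext = ".png")
  write_mask(matrix(FALSE, 3, 3), p0)
  expect_identical(sum(read_mask(p0)), 0L)

  # intermediate gray value counts as positive
  pg <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(c(0, 128 / 255, 0, 0), 2, 2), pg)
  expect_identical(sum(read_mask(pg)), 1L)

  # multi-channel image rejected
  prgb <- withr::local_tempfile(fileext = ".png")
  png::writePNG(array(0.5, dim = c(2, 2, 3)), prgb)
  expect_error(read_mask(prgb), class = "hsderm_format_error")
})

test_that("reference library CSV round-trips and validates", {
  wl <- seq(450, 950, length.out = 10)
  lib <- spectral_library(
    name = c("skin_1", "skin_2", "skin_3", "benign", "malignant"),
    class = c("skin", "skin", "skin", "benign", "malignant"),
    spectra = matrix(runif(50), 5), wavelengths_nm = wl)
  path <- withr::local_tempfile(fileext = ".csv")
  write_library(lib, path)
  back <- read_library(path)
  expect_identical(length(back), 5L)
  expect_identical(back$name, lib$name)
  expect_identical(back$class, lib$class)
  expect_equal(back$spectra, lib$spectra, tolerance = 1e-12)
  expect_equal(back$wavelengths_nm, wl)

  # empty CSV -> error
  pe <- withr::local_tempfile(fileext = ".csv")
  writeLines("name,class,450,500", pe)
  expect_error(read_library(pe), class = "hsderm_format_error")

  # duplicate names / bad class rejected at construction
  expect_error(spectral_library(c("a", "a"), c("skin", "skin"),
                                matrix(1, 2, 3), 1:3),
               class = "hsderm_format_error")
  expect_error(spectral_library("a", "tumor", matrix(1, 1, 3), 1:3),
               class = "hsderm_format_error")
})

test_that("labeled spectra CSV round-trips with identifiers intact", {
  set <- separable_set(n_per_class = 5, bands = 6)
  path <- withr::local_tempfile(fileext = ".csv")
  write_labeled_spectra(set, path)
  back <- read_labeled_spectra(path)
  expect_identical(back$class, set$class)
  expect_identical(back$patient_id, set$patient_id)
  expect_identical(back$image_id, set$image_id)
  expect_equal(back$spectra, set$spectra, tolerance = 1e-12)
})
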