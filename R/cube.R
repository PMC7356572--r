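#' Hyperspectral cube
#'
#' A 3-D reflectance (or raw count) raster: `rows x cols x bands`, with a
#' strictly increasing wavelength axis and a calibration state that records
#' where the cube sits in the processing chain (`raw` sensor counts,
#' `calibrated` reflectance, or `preprocessed` trimmed/smoothed/normalized
#' reflectance).
#'
#' @param values Numeric array `rows x cols x bands`.
#' @param wavelengths_nm Numeric vector of band-center wavelengths, one per
#'   band, strictly increasing.
#' @param state One of `"raw"`, `"calibrated"`, `"preprocessed"`.
#' @return An object of class `hs_cube`.
#' @export
hs_cube <- function(values, wavelengths_nm,
                    state = c("raw", "calibrated", "preprocessed")) {
  state <- match.arg(state)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop_contract("values must be a rows x cols x bands array")
  wavelengths_nm <- as.numeric(wavelengths_nm)
  if (dim(values)[3L] != length(wavelengths_nm))
    stop_format("band count (", dim(values)[3L],
                ") does not match wavelength list length (",
                length(wavelengths_nm), ")")
  if (length(wavelengths_nm) > 1L && any(diff(wavelengths_nm) <= 0))
    stop_contract("wavelengths must be strictly increasing")
  structure(list(values = values, wavelengths_nm = wavelengths_nm,
                 state = state), class = "hs_cube")
}

#' @export
print.hs_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<hs_cube> %d x %d px, %d bands %.1f-%.1f nm, state: %s\n",
              d[1], d[2], d[3], min(x$wavelengths_nm), max(x$wavelengths_nm),
              x$state))
  invisible(x)
}

#' @export
dim.hs_cube <- function(x) dim(x$values)

n_bands <- function(cube) dim(cube$values)[3L]

#' Extract the pixel-by-band spectra matrix of a cube
#'
#' Flattens the spatial grid in row-major order (row 1 pixels first, left to
#' right), giving a `(rows*cols) x bands` matrix whose row `i` is the
#' spectral signature of pixel `((i-1) %/% cols + 1, (i-1) %% cols + 1)`.
#'
#' @param cube An `hs_cube`.
#' @return Numeric matrix with one spectrum per row.
#' @export
cube_spectra <- function(cube) {
  d <- dim(cube$values)
  # aperm to (col, row, band) then fold: makes pixel order row-major
  m <- matrix(aperm(cube$values, c(2L, 1L, 3L)), nrow = d[1L] * d[2L],
              ncol = d[3L])
  m
}

# Inverse of cube_spectra for per-pixel scalar/vector fields: reshape a
# row-major pixel vector back into a rows x cols matrix.
pixel_field <- function(v, rows, cols) {
  matrix(v, nrow = rows, ncol = cols, byrow = TRUE)
}

#' White and dark reference frames used for radiometric calibration
#'
#' @param white,dark `hs_cube`s in raw state, shaped like the cubes they
#'   calibrate.
#' @return An object of class `ref_frames`.
#' @export
ref_frames <- function(white, dark) {
  stopifnot(inherits(white, "hs_cube"), inherits(dark, "hs_cube"))
  if (!identical(dim(white$values), dim(dark$values)))
    stop_contract("white and dark frames must share shape")
  if (!isTRUE(all.equal(white$wavelengths_nm, dark$wavelengths_nm)))
    stop_contract("white and dark frames must share the wavelength grid")
  structure(list(white = white, dark = dark), class = "ref_frames")
}
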