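#' Instrument profile of the snapshot VNIR dermatology camera
#'
#' Describes the acquisition geometry the rest of the package assumes: a
#' snapshot hyperspectral camera producing 50 x 50 pixel cubes with 125
#' contiguous bands between 450 and 950 nm (about 4 nm sampling; the 8 nm
#' figure is the FWHM spectral resolution, not the sampling step) over an
#' effective skin area of 12 x 12 mm.
#'
#' @param n_bands Number of spectral bands.
#' @param lambda_min_nm,lambda_max_nm First and last band-center wavelengths
#'   in nanometres.
#' @param spatial_rows,spatial_cols Spatial raster size in pixels.
#' @param spectral_resolution_nm FWHM spectral resolution in nanometres.
#' @param effective_area_mm Side length of the imaged square skin area (mm).
#' @return An object of class `instrument_profile`: a list with the fields
#'   above plus `wavelengths_nm`, the uniform band-center grid.
#' @examples
#' p <- instrument_profile()
#' length(p$wavelengths_nm)  # 125
#' @export
instrument_profile <- function(n_bands = 125L,
                               lambda_min_nm = 450,
                               lambda_max_nm = 950,
                               spatial_rows = 50L,
                               spatial_cols = 50L,
                               spectral_resolution_nm = 8,
                               effective_area_mm = 12) {
  n_bands <- as.integer(n_bands)
  if (n_bands < 2L) stop_contract("instrument profile needs at least 2 bands")
  if (!(lambda_min_nm < lambda_max_nm))
    stop_contract("lambda_min_nm must be smaller than lambda_max_nm")
  structure(list(
    n_bands = n_bands,
    lambda_min_nm = lambda_min_nm,
    lambda_max_nm = lambda_max_nm,
    spatial_rows = as.integer(spatial_rows),
    spatial_cols = as.integer(spatial_cols),
    spectral_resolution_nm = spectral_resolution_nm,
    effective_area_mm = effective_area_mm,
    wavelengths_nm = seq(lambda_min_nm, lambda_max_nm, length.out = n_bands)
  ), class = "instrument_profile")
}

#' @export
print.instrument_profile <- function(x, ...) {
  cat(sprintf("<instrument_profile> %d x %d px, %d bands %.0f-%.0f nm (FWHM %.0f nm)\n",
              x$spatial_rows, x$spatial_cols, x$n_bands,
              x$lambda_min_nm, x$lambda_max_nm, x$spectral_resolution_nm))
  invisible(x)
}
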