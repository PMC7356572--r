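# Pre-processing chain: radiometric calibration against white/dark
# references, trimming of low-response edge bands, spectral smoothing, and
# per-signature min-max normalization so only the shape of each spectrum
# (not its illumination-dependent amplitude) is carried forward.

#' Pre-processing configuration
#'
#' @param drop_first,drop_last Number of leading/trailing bands removed for
#'   low sensor response (defaults 4 and 5: 125 raw bands become 116).
#' @param smooth_window Odd moving-average window (bands) for spectral
#'   smoothing; 1 disables smoothing.
#' @param normalize Apply per-signature min-max normalization to [0, 1].
#' @param clamp_negative Clamp negative calibrated reflectance to 0.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(drop_first = 4L, drop_last = 5L,
                              smooth_window = 5L, normalize = TRUE,
                              clamp_negative = TRUE) {
  smooth_window <- as.integer(smooth_window)
  if (smooth_window < 1L || smooth_window %% 2L == 0L)
    stop_contract("smooth_window must be odd and >= 1")
  structure(list(drop_first = as.integer(drop_first),
                 drop_last = as.integer(drop_last),
                 smooth_window = smooth_window,
                 normalize = isTRUE(normalize),
                 clamp_negative = isTRUE(clamp_negative)),
            class = "preprocess_config")
}

#' Radiometric calibration of a raw cube
#'
#' Converts raw sensor counts to relative reflectance using a white
#' reference capture (tile reflecting ~99% of incident light) and a dark
#' reference (shutter closed): `CI = (RI - DI) / (WI - DI)` voxelwise.
#' Dead voxels where white equals dark are set to 0 and counted in the
#' `n_dead_voxels` attribute rather than aborting the capture; negative
#' reflectance (raw below dark) is clamped to 0 when `clamp_negative`.
#'
#' @param raw Raw [hs_cube()].
#' @param refs [ref_frames()] sharing shape and wavelength grid with `raw`.
#' @param cfg A [preprocess_config()].
#' @return A calibrated [hs_cube()] with attribute `n_dead_voxels`.
#' @export
calibrate <- function(raw, refs, cfg = preprocess_config()) {
  stopifnot(inherits(raw, "hs_cube"), inherits(refs, "ref_frames"))
  if (!identical(dim(raw$values), dim(refs$white$values)))
    stop_contract("raw and reference frames must share shape")
  if (!isTRUE(all.equal(raw$wavelengths_nm, refs$white$wavelengths_nm)))
    stop_contract("raw and reference frames must share the wavelength grid")
  denom <- refs$white$values - refs$dark$values
  dead <- denom == 0
  denom[dead] <- 1
  ci <- (raw$values - refs$dark$values) / denom
  ci[dead] <- 0
  if (cfg$clamp_negative) ci[ci < 0] <- 0
  out <- hs_cube(ci, raw$wavelengths_nm, state = "calibrated")
  attr(out, "n_dead_voxels") <- sum(dead)
  out
}

#' Remove low-response edge bands
#'
#' @param cube An [hs_cube()].
#' @param cfg A [preprocess_config()]; `drop_first` leading and `drop_last`
#'   trailing bands are removed (125 -> 116 with the defaults).
#' @return The trimmed [hs_cube()].
#' @export
trim_bands <- function(cube, cfg = preprocess_config()) {
  stopifnot(inherits(cube, "hs_cube"))
  nb <- n_bands(cube)
  if (cfg$drop_first + cfg$drop_last >= nb)
    stop_contract("drop_first + drop_last (", cfg$drop_first + cfg$drop_last,
                  ") must be smaller than the band count (", nb, ")")
  keep <- seq.int(cfg$drop_first + 1L, nb - cfg$drop_last)
  hs_cube(cube$values[, , keep, drop = FALSE], cube$wavelengths_nm[keep],
          state = cube$state)
}

# centered moving average with truncated windows at the spectral edges
moving_average <- function(s, window) {
  if (window == 1L) return(s)
  h <- (window - 1L) %/% 2L
  n <- length(s)
  cs <- cumsum(c(0, s))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L); hi <- pmin(i + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Smooth each pixel's spectrum with a centered moving average
#'
#' Edge bands are averaged over the truncated in-range part of the window;
#' the spatial grid is untouched.
#'
#' @inheritParams trim_bands
#' @return The smoothed [hs_cube()].
#' @export
smooth_spectra <- function(cube, cfg = preprocess_config()) {
  stopifnot(inherits(cube, "hs_cube"))
  w <- cfg$smooth_window
  if (w %% 2L == 0L) stop_contract("smooth_window must be odd")
  if (w > n_bands(cube)) stop_contract("smooth_window exceeds band count")
  if (w == 1L) return(cube)
  d <- dim(cube$values)
  v <- array(apply(cube$values, c(1L, 2L), moving_average, window = w),
             dim = c(d[3L], d[1L], d[2L]))
  hs_cube(aperm(v, c(2L, 3L, 1L)), cube$wavelengths_nm, state = cube$state)
}

#' Min-max normalize every spectral signature to [0, 1]
#'
#' Each pixel's spectrum is mapped to `(s - min(s)) / (max(s) - min(s))`,
#' which removes amplitude differences caused by non-uniform illumination so
#' downstream methods see only the spectral shape. Flat spectra (max = min)
#' map to all-zeros.
#'
#' @param cube A calibrated [hs_cube()].
#' @return The normalized [hs_cube()] in `preprocessed` state.
#' @export
normalize_minmax <- function(cube) {
  stopifnot(inherits(cube, "hs_cube"))
  d <- dim(cube$values)
  lo <- apply(cube$values, c(1L, 2L), min)
  hi <- apply(cube$values, c(1L, 2L), max)
  rng <- hi - lo
  flat <- rng == 0
  rng[flat] <- 1
  v <- sweep(cube$values, c(1L, 2L), lo, "-")
  v <- sweep(v, c(1L, 2L), rng, "/")
  if (any(flat)) v[array(flat, dim = d)] <- 0
  hs_cube(v, cube$wavelengths_nm, state = "preprocessed")
}

#' Full pre-processing chain
#'
#' Calibration, band trimming, spectral smoothing and (optionally)
#' per-signature normalization, in that order.
#'
#' @inheritParams calibrate
#' @return The pre-processed [hs_cube()] (state `preprocessed` when
#'   `cfg$normalize`, else `calibrated`).
#' @export
preprocess_chain <- function(raw, refs, cfg = preprocess_config()) {
  out <- calibrate(raw, refs, cfg)
  out <- trim_bands(out, cfg)
  out <- smooth_spectra(out, cfg)
  if (cfg$normalize) out <- normalize_minmax(out)
  out
}
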