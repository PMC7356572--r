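# Acquisition repeatability analysis: paired-capture scatter data, the
# absolute relative difference percentage, and masked spectral statistics.

#' Absolute relative difference (%) between two paired captures
#'
#' Voxelwise `RD = |x - y| * 100 / ((mean(x) + mean(y)) / 2)`, where the
#' means are taken over each full array; `rd_mean` is the arithmetic mean of
#' the voxel map. Lower values indicate higher repeatability. RD is
#' symmetric in its arguments and invariant to scaling both by the same
#' positive factor.
#'
#' @param x,y Numeric arrays (or `hs_cube`s) of identical shape.
#' @return A list of class `repeatability_report`: `rd_map` (same shape as
#'   the input), `rd_mean` and `n_voxels`.
#' @export
relative_difference <- function(x, y) {
  if (inherits(x, "hs_cube")) x <- x$values
  if (inherits(y, "hs_cube")) y <- y$values
  if (!identical(dim2(x), dim2(y)) || length(x) != length(y))
    stop_contract("x and y must share shape")
  denom <- (mean(x) + mean(y)) / 2
  if (!(denom > 0)) stop_contract("mean(x) + mean(y) must be positive")
  rd <- abs(x - y) * 100 / denom
  structure(list(rd_map = rd, rd_mean = mean(rd), n_voxels = length(rd)),
            class = "repeatability_report")
}

dim2 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

#' @export
print.repeatability_report <- function(x, ...) {
  cat(sprintf("<repeatability_report> RDmean = %.2f%% over %d voxels\n",
              x$rd_mean, x$n_voxels))
  invisible(x)
}

#' Per-band mean and variance of the spectra under a mask
#'
#' Summarizes the spectral signatures of the masked (lesion) pixels:
#' per-band mean and population variance (divide by n).
#'
#' @param cube An [hs_cube()].
#' @param mask Logical matrix matching the cube's spatial grid, with at
#'   least one `TRUE` pixel.
#' @return A list with `mean` and `variance` (numeric, one per band),
#'   `n_pixels`, and `wavelengths_nm`.
#' @export
masked_spectral_stats <- function(cube, mask) {
  stopifnot(inherits(cube, "hs_cube"))
  d <- dim(cube$values)
  if (!is.matrix(mask) || !identical(dim(mask), d[1:2]))
    stop_contract("mask shape must match the cube's spatial grid")
  sel <- which(t(mask))  # row-major pixel index
  if (length(sel) == 0L) stop_contract("mask has no positive pixels")
  sp <- cube_spectra(cube)[sel, , drop = FALSE]
  mu <- colMeans(sp)
  v <- colMeans(sp^2) - mu^2
  v[v < 0] <- 0  # numeric guard
  list(mean = mu, variance = v, n_pixels = length(sel),
       wavelengths_nm = cube$wavelengths_nm)
}

#' Paired voxel values of two co-registered cubes
#'
#' Flattens both cubes into an aligned two-column matrix of voxel pairs
#' (pixels in row-major order, bands innermost), the raw material of a
#' repeatability scatterplot: for identical captures all pairs lie on the
#' identity line.
#'
#' @param a,b `hs_cube`s of identical shape.
#' @return A numeric matrix with columns `a` and `b` and
#'   `rows * cols * bands` rows.
#' @export
scatter_pairs <- function(a, b) {
  stopifnot(inherits(a, "hs_cube"), inherits(b, "hs_cube"))
  if (!identical(dim(a$values), dim(b$values)))
    stop_contract("cubes must share shape")
  va <- as.vector(t(cube_spectra(a)))  # pixel-major, band innermost
  vb <- as.vector(t(cube_spectra(b)))
  cbind(a = va, b = vb)
}
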