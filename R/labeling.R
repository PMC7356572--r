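# Spectral Angle Mapper similarity and the SAM-guided labeling tool: grow a
# labeled region from a manually chosen reference pixel by marking every
# pixel whose spectral angle to it falls under a threshold.

#' Spectral angle between two signatures (SAM)
#'
#' The angle between two spectra treated as vectors:
#' `acos(<s1, s2> / (||s1|| ||s2||))`, with the cosine clipped to [-1, 1]
#' for numerical safety. Lower angles mean higher spectral similarity; the
#' measure is symmetric and invariant to positive scaling of either
#' argument, which makes it robust to illumination amplitude differences.
#'
#' @param s1,s2 Numeric vectors of equal length, neither all-zero.
#' @return Angle in radians, in `[0, pi]`.
#' @export
sam_angle <- function(s1, s2) {
  if (length(s1) != length(s2))
    stop_contract("spectra must have equal length")
  n1 <- sqrt(sum(s1^2)); n2 <- sqrt(sum(s2^2))
  if (n1 == 0 || n2 == 0) stop_contract("SAM is undefined for zero vectors")
  acos(min(1, max(-1, sum(s1 * s2) / (n1 * n2))))
}

# SAM of every row of `m` against vector `ref`; rows that are all-zero get
# NA (no direction). Vectorized version of sam_angle for pixel matrices.
sam_angles_matrix <- function(m, ref) {
  nref <- sqrt(sum(ref^2))
  if (nref == 0) stop_contract("SAM is undefined for zero vectors")
  nm <- sqrt(rowSums(m^2))
  cosv <- as.vector(m %*% ref) / (nm * nref)
  ang <- acos(pmin(1, pmax(-1, cosv)))
  ang[nm == 0] <- NA_real_
  ang
}

#' Grow a labeled region from a reference pixel by spectral similarity
#'
#' Marks every pixel of the cube whose SAM angle to the seed pixel's
#' spectrum is at or below `threshold` (the seed itself is always marked).
#' The test is global — purely spectral, with no spatial-connectivity
#' constraint — so spectrally identical pixels anywhere in the image are
#' labeled. A tiny angular tolerance (1e-6 rad) absorbs floating-point
#' round-off so that `threshold = 0` captures exactly the pixels equal to
#' the seed up to positive scaling.
#'
#' @param cube A preprocessed [hs_cube()].
#' @param seed Integer vector `c(row, col)` of the reference pixel (1-based).
#' @param threshold Maximum SAM angle in radians (>= 0).
#' @return Logical `rows x cols` mask.
#' @export
grow_labels <- function(cube, seed, threshold) {
  stopifnot(inherits(cube, "hs_cube"))
  d <- dim(cube$values)
  seed <- as.integer(seed)
  if (length(seed) != 2L || seed[1L] < 1L || seed[1L] > d[1L] ||
      seed[2L] < 1L || seed[2L] > d[2L])
    stop_contract("seed pixel out of bounds")
  if (threshold < 0) stop_contract("threshold must be >= 0")
  ref <- cube$values[seed[1L], seed[2L], ]
  ang <- sam_angles_matrix(cube_spectra(cube), ref)
  hit <- !is.na(ang) & ang <= threshold + 1e-6
  mask <- pixel_field(hit, d[1L], d[2L])
  mask[seed[1L], seed[2L]] <- TRUE
  mask
}
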