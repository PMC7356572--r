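# Seeded synthetic dermatologic scenes with known ground truth. The
# spectral model is phenomenological: VNIR skin reflectance rises
# logistically from the visible toward a near-infrared plateau, carries
# the oxyhemoglobin absorption dips near 542 and 576 nm, and is attenuated
# by a melanin factor exp(-m * (500 / lambda)^3) that darkens pigmented
# tissue progressively toward short wavelengths. Lesions differ from skin
# (and malignant from benign) in pigmentation and slope, not just
# amplitude, so classes stay separable after per-signature normalization.

#' Parameters of the phenomenological skin/lesion reflectance model
#'
#' @param base_level Reflectance at the blue end, before melanin
#'   attenuation.
#' @param nir_plateau Reflectance plateau reached in the near infrared.
#' @param slope_center_nm,slope_width_nm Center and width of the logistic
#'   rise between the two levels.
#' @param dip_542,dip_576 Depths of the Gaussian oxyhemoglobin absorption
#'   dips at 542 and 576 nm.
#' @param melanin_scale Strength of the melanin attenuation
#'   `exp(-melanin_scale * (500/lambda)^3)`; higher = darker tissue.
#' @return A list of class `spectral_model_params`.
#' @export
spectral_model_params <- function(base_level = 0.15, nir_plateau = 0.65,
                                  slope_center_nm = 585,
                                  slope_width_nm = 40,
                                  dip_542 = 0.04, dip_576 = 0.03,
                                  melanin_scale = 0.3) {
  structure(list(base_level = base_level, nir_plateau = nir_plateau,
                 slope_center_nm = slope_center_nm,
                 slope_width_nm = slope_width_nm,
                 dip_542 = dip_542, dip_576 = dip_576,
                 melanin_scale = melanin_scale),
            class = "spectral_model_params")
}

#' Default spectral parameter sets: three skin types and two lesion classes
#'
#' The three normal-skin modes differ mainly in melanin content (light to
#' dark skin types); benign lesions are more pigmented than any normal
#' skin, and malignant lesions are darker still with a flatter, red-shifted
#' rise, giving all class-mean pairs a spectral angle of at least 0.05 rad
#' after preprocessing.
#'
#' @return A named list: `skin` (list of 3 [spectral_model_params()]),
#'   `benign`, `malignant`.
#' @export
default_spectral_params <- function() {
  list(
    skin = list(
      spectral_model_params(melanin_scale = 0.10, dip_542 = 0.055,
                            dip_576 = 0.045, slope_center_nm = 580),
      spectral_model_params(melanin_scale = 0.60, dip_542 = 0.030,
                            dip_576 = 0.022, slope_center_nm = 592),
      spectral_model_params(melanin_scale = 1.20, dip_542 = 0.015,
                            dip_576 = 0.010, slope_center_nm = 604)
    ),
    benign = spectral_model_params(base_level = 0.10, nir_plateau = 0.55,
                                   slope_center_nm = 620,
                                   slope_width_nm = 50,
                                   dip_542 = 0.02, dip_576 = 0.015,
                                   melanin_scale = 1.8),
    malignant = spectral_model_params(base_level = 0.08, nir_plateau = 0.45,
                                      slope_center_nm = 670,
                                      slope_width_nm = 70,
                                      dip_542 = 0.01, dip_576 = 0.008,
                                      melanin_scale = 2.8)
  )
}

#' Generate a reflectance spectrum from model parameters
#'
#' @param params A [spectral_model_params()].
#' @param wavelengths_nm Wavelength grid in nm.
#' @return Reflectance vector, clipped to (0, 1).
#' @export
make_spectrum <- function(params, wavelengths_nm) {
  stopifnot(inherits(params, "spectral_model_params"))
  wl <- as.numeric(wavelengths_nm)
  s <- params$base_level + (params$nir_plateau - params$base_level) /
    (1 + exp(-(wl - params$slope_center_nm) / params$slope_width_nm))
  s <- s - params$dip_542 * exp(-(wl - 542)^2 / (2 * 12^2))
  s <- s - params$dip_576 * exp(-(wl - 576)^2 / (2 * 12^2))
  s <- s * exp(-params$melanin_scale * (500 / wl)^3)
  pmin(1 - 1e-3, pmax(1e-3, s))
}

#' Scene configuration for the synthetic generator
#'
#' @param profile An [instrument_profile()].
#' @param skin_type Index (1-3) into the default normal-skin modes.
#' @param lesion_class `"none"`, `"benign"` or `"malignant"`.
#' @param lesion_radius_px Mean lesion radius in pixels.
#' @param lesion_center `c(row, col)` of the lesion center (defaults to the
#'   grid center).
#' @param illumination_gradient Relative amplitude of the smooth
#'   multiplicative illumination non-uniformity (default 0.1).
#' @param noise_sd Per-voxel Gaussian reflectance noise (default 0.01).
#' @param seed Integer seed; the whole scene is a pure function of the
#'   config.
#' @return A list of class `scene_config`.
#' @export
scene_config <- function(profile = instrument_profile(), skin_type = 1L,
                         lesion_class = c("benign", "malignant", "none"),
                         lesion_radius_px = 9, lesion_center = NULL,
                         illumination_gradient = 0.1, noise_sd = 0.01,
                         seed = 1L) {
  lesion_class <- match.arg(lesion_class)
  if (is.null(lesion_center))
    lesion_center <- c(ceiling(profile$spatial_rows / 2),
                       ceiling(profile$spatial_cols / 2))
  if (noise_sd < 0) stop_contract("noise_sd must be >= 0")
  r_max <- lesion_radius_px * 1.3  # jitter headroom
  if (lesion_class != "none" &&
      (lesion_center[1L] - r_max < 1 ||
       lesion_center[1L] + r_max > profile$spatial_rows ||
       lesion_center[2L] - r_max < 1 ||
       lesion_center[2L] + r_max > profile$spatial_cols))
    stop_contract("lesion does not fit inside the spatial grid")
  structure(list(profile = profile, skin_type = as.integer(skin_type),
                 lesion_class = lesion_class,
                 lesion_radius_px = lesion_radius_px,
                 lesion_center = as.numeric(lesion_center),
                 illumination_gradient = illumination_gradient,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "scene_config")
}

# elliptical lesion footprint with smooth seeded boundary jitter
lesion_footprint <- function(rows, cols, center, radius) {
  aspect <- stats::runif(1, 0.7, 1)
  theta0 <- stats::runif(1, 0, pi)
  a1 <- stats::rnorm(1, 0, 0.06); b1 <- stats::rnorm(1, 0, 0.06)
  a2 <- stats::rnorm(1, 0, 0.04); b2 <- stats::rnorm(1, 0, 0.04)
  rr <- matrix(seq_len(rows), rows, cols) - center[1L]
  cc <- matrix(seq_len(cols), rows, cols, byrow = TRUE) - center[2L]
  u <- cos(theta0) * rr + sin(theta0) * cc
  v <- (-sin(theta0) * rr + cos(theta0) * cc) / aspect
  ang <- atan2(v, u)
  jitter <- 1 + a1 * cos(ang) + b1 * sin(ang) +
    a2 * cos(2 * ang) + b2 * sin(2 * ang)
  sqrt(u^2 + v^2) <= radius * jitter
}

#' Generate one synthetic dermatologic capture with ground truth
#'
#' Builds a per-pixel reflectance field (normal skin of the configured
#' type, with an optional compact lesion blob), adds seeded Gaussian
#' reflectance noise, and maps it through the forward acquisition model:
#' `raw = reflectance * (white - dark) + dark` plus small count noise, with
#' a smooth multiplicative illumination gradient applied to the white frame
#' and the raw counts alike (so radiometric calibration cancels it).
#'
#' @param cfg A [scene_config()].
#' @return A list of class `hs_scene`: `raw` (raw [hs_cube()]), `refs`
#'   ([ref_frames()]), `gt_mask` (logical ground-truth lesion mask),
#'   `lesion_class`, `reflectance` (the noisy ground-truth reflectance
#'   array), and `cfg`.
#' @export
make_scene <- function(cfg = scene_config()) {
  stopifnot(inherits(cfg, "scene_config"))
  p <- cfg$profile
  rows <- p$spatial_rows; cols <- p$spatial_cols; nb <- p$n_bands
  wl <- p$wavelengths_nm
  pars <- default_spectral_params()
  skin_spec <- make_spectrum(pars$skin[[cfg$skin_type]], wl)
  with_seed(cfg$seed, {
    if (cfg$lesion_class == "none") {
      mask <- matrix(FALSE, rows, cols)
    } else {
      mask <- lesion_footprint(rows, cols, cfg$lesion_center,
                               cfg$lesion_radius_px)
    }
    refl <- array(rep(skin_spec, each = rows * cols), dim = c(rows, cols, nb))
    if (any(mask)) {
      lesion_spec <- make_spectrum(pars[[cfg$lesion_class]], wl)
      for (b in seq_len(nb)) {
        plane <- refl[, , b]
        plane[mask] <- lesion_spec[b]
        refl[, , b] <- plane
      }
    }
    refl <- refl + array(stats::rnorm(length(refl), sd = cfg$noise_sd),
                         dim = dim(refl))
    refl <- pmin(1 - 1e-4, pmax(1e-4, refl))
    # smooth multiplicative illumination gradient (planar ramp)
    g_dir <- stats::runif(1, 0, 2 * pi)
    ramp <- cos(g_dir) * (matrix(seq_len(rows), rows, cols) / rows - 0.5) +
      sin(g_dir) * (matrix(seq_len(cols), rows, cols, byrow = TRUE) / cols - 0.5)
    illum <- 1 + cfg$illumination_gradient * ramp / max(abs(ramp))
    white_level <- 3000; dark_level <- 100
    white <- array(rep(illum, nb) * white_level, dim = c(rows, cols, nb)) +
      array(stats::rnorm(rows * cols * nb, sd = 5), dim = c(rows, cols, nb))
    dark <- array(dark_level, dim = c(rows, cols, nb)) +
      array(stats::rnorm(rows * cols * nb, sd = 2), dim = c(rows, cols, nb))
    raw <- refl * (white - dark) + dark +
      array(stats::rnorm(rows * cols * nb, sd = 2), dim = c(rows, cols, nb))
    structure(list(
      raw = hs_cube(raw, wl, state = "raw"),
      refs = ref_frames(hs_cube(white, wl, state = "raw"),
                        hs_cube(dark, wl, state = "raw")),
      gt_mask = mask, lesion_class = cfg$lesion_class,
      reflectance = refl, cfg = cfg), class = "hs_scene")
  })
}

#' @export
print.hs_scene <- function(x, ...) {
  cat(sprintf("<hs_scene> %s lesion, %d ground-truth lesion pixels, seed %d\n",
              x$lesion_class, sum(x$gt_mask), x$cfg$seed))
  invisible(x)
}

#' Generate a multi-patient synthetic labeled dataset
#'
#' Emulates the structure of a clinical campaign: each patient has a fixed
#' skin type, contributes one or more captured scenes, and labeled pixel
#' spectra are sampled from the scenes' ground-truth regions (lesion pixels
#' with the lesion's diagnostic class, surrounding pixels as normal skin)
#' after full preprocessing, with patient and image identifiers attached.
#'
#' @param n_patients Number of patients (>= 1).
#' @param images_per_patient Scenes captured per patient.
#' @param class_mix Named lesion-class composition of the campaign; image
#'   counts per class follow these proportions exactly (largest-remainder
#'   allocation, shuffled across images). The default mirrors the clinical
#'   image mix (40 benign / 36 malignant).
#' @param seed Integer master seed.
#' @param n_lesion_px,n_skin_px Labeled pixels sampled per image from the
#'   lesion and the normal-skin region.
#' @param profile An [instrument_profile()].
#' @param keep_scenes Keep the generated scenes in the result (memory-heavy
#'   for large campaigns; default drops them).
#' @return A list of class `hs_dataset`: `labeled` (a
#'   [labeled_spectra()] on the preprocessed 116-band grid), `scene_info`
#'   (data.frame of patient/image/class/skin type/seed), and optionally
#'   `scenes`.
#' @export
make_dataset <- function(n_patients = 12L, images_per_patient = 1L,
                         class_mix = c(benign = 40, malignant = 36) / 76,
                         seed = 1L, n_lesion_px = 100L, n_skin_px = 100L,
                         profile = instrument_profile(),
                         keep_scenes = FALSE) {
  n_patients <- as.integer(n_patients)
  if (n_patients < 1L) stop_contract("n_patients must be >= 1")
  class_mix <- class_mix / sum(class_mix)
  plan <- with_seed(seed, {
    data.frame(
      patient_id = rep(sprintf("P%03d", seq_len(n_patients)),
                       each = images_per_patient),
      image_id = paste0(rep(sprintf("P%03d", seq_len(n_patients)),
                            each = images_per_patient), "_C",
                        rep(seq_len(images_per_patient), n_patients)),
      skin_type = rep(sample(rep_len(1:3, n_patients)),
                      each = images_per_patient),
      # fixed campaign composition: class counts follow the mix exactly
      # (largest-remainder rounding), shuffled across images
      lesion_class = sample(rep(names(class_mix), diff(round(
        cumsum(c(0, class_mix)) * n_patients * images_per_patient)))),
      radius = stats::runif(n_patients * images_per_patient, 6, 11),
      scene_seed = sample.int(.Machine$integer.max - 1L,
                              n_patients * images_per_patient),
      stringsAsFactors = FALSE)
  })
  scenes <- vector("list", nrow(plan))
  labeled <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    cfg <- scene_config(profile = profile, skin_type = plan$skin_type[i],
                        lesion_class = plan$lesion_class[i],
                        lesion_radius_px = plan$radius[i],
                        seed = plan$scene_seed[i])
    sc <- make_scene(cfg)
    pre <- preprocess_chain(sc$raw, sc$refs)
    sp <- cube_spectra(pre)
    lesion_idx <- which(t(sc$gt_mask))
    skin_idx <- which(!t(sc$gt_mask))
    pick <- with_seed(plan$scene_seed[i] + 1L, list(
      lesion = if (length(lesion_idx))
        sample(lesion_idx, min(n_lesion_px, length(lesion_idx))) else integer(0),
      skin = sample(skin_idx, min(n_skin_px, length(skin_idx)))))
    idx <- c(pick$lesion, pick$skin)
    labeled[[i]] <- labeled_spectra(
      sp[idx, , drop = FALSE],
      c(rep(plan$lesion_class[i], length(pick$lesion)),
        rep("skin", length(pick$skin))),
      rep(plan$patient_id[i], length(idx)),
      rep(plan$image_id[i], length(idx)),
      pre$wavelengths_nm)
    if (keep_scenes) scenes[[i]] <- sc
  }
  structure(list(labeled = do.call(bind_labeled, labeled),
                 scene_info = plan,
                 scenes = if (keep_scenes) scenes else NULL),
            class = "hs_dataset")
}

#' @export
print.hs_dataset <- function(x, ...) {
  cat(sprintf("<hs_dataset> %d images from %d patients, %d labeled spectra\n",
              nrow(x$scene_info), length(unique(x$scene_info$patient_id)),
              nrow(x$labeled$spectra)))
  invisible(x)
}
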