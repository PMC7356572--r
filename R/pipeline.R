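# End-to-end clinical-support framework: pre-process the raw capture,
# segment lesion pixels, classify only those pixels, and issue a
# lesion-level decision using the malignant-pixel risk threshold. Also the
# patient-stratified partition used to train and validate the models.

#' Split specification for the patient-stratified partition
#'
#' @param fractions Numeric `c(train, val, test)` target pixel fractions,
#'   all positive, summing to 1. The default mirrors the clinical pixel
#'   proportions (11558 / 1931 / 2472 labeled pixels).
#' @param seed Integer seed for the patient shuffle.
#' @return A list of class `split_spec`.
#' @export
split_spec <- function(fractions = c(train = 11558, val = 1931,
                                     test = 2472) / 15961,
                       seed = 1L) {
  if (length(fractions) != 3L || any(fractions <= 0))
    stop_contract("fractions must be 3 positive numbers")
  fractions <- fractions / sum(fractions)
  names(fractions) <- c("train", "val", "test")
  structure(list(fractions = fractions, seed = as.integer(seed)),
            class = "split_spec")
}

#' Patient-stratified train/validation/test split
#'
#' Every patient's pixels land in exactly one of the three sets, so no
#' patient can contribute to both model fitting and evaluation. Patients
#' are shuffled with the spec's seed and assigned greedily: each patient
#' goes to the set whose pixel share is currently furthest below its
#' target. Afterwards, if the validation or test set lacks a lesion class
#' that the pool could supply, a donor patient with that class is moved in
#' from the training set (feasibility permitting).
#'
#' @param data A [labeled_spectra()] with at least 3 distinct patients.
#' @param spec A [split_spec()].
#' @return A named list of three [labeled_spectra()]: `train`, `val`,
#'   `test`.
#' @export
patient_stratified_split <- function(data, spec = split_spec()) {
  stopifnot(inherits(data, "labeled_spectra"), inherits(spec, "split_spec"))
  patients <- unique(data$patient_id)
  if (length(patients) < 3L)
    stop_contract("need at least 3 distinct patients")
  n_px <- table(data$patient_id)
  total <- nrow(data$spectra)
  assign_set <- with_seed(spec$seed, {
    shuffled <- sample(patients)
    sizes <- c(train = 0, val = 0, test = 0)
    out <- stats::setNames(character(length(shuffled)), shuffled)
    for (p in shuffled) {
      deficit <- spec$fractions - sizes / total
      tgt <- names(which.max(deficit))
      out[p] <- tgt
      sizes[tgt] <- sizes[tgt] + n_px[[p]]
    }
    out
  })
  # ensure each set is non-empty patient-wise (>=3 patients guarantee)
  for (s in c("train", "val", "test")) {
    if (!any(assign_set == s)) {
      donor_set <- names(which.max(table(assign_set)))
      donor <- names(assign_set)[assign_set == donor_set][1L]
      assign_set[donor] <- s
    }
  }
  # feasibility fix: val/test should see both lesion classes when possible
  patient_classes <- function(p)
    unique(data$class[data$patient_id == p & data$class %in% .lesion_classes])
  for (s in c("val", "test")) {
    have <- unique(unlist(lapply(names(assign_set)[assign_set == s],
                                 patient_classes)))
    for (cls in setdiff(.lesion_classes, have)) {
      donors <- names(assign_set)[assign_set == "train"]
      donors <- donors[vapply(donors, function(p) cls %in% patient_classes(p),
                              logical(1))]
      if (length(donors) > 1L) {  # keep train populated
        donor <- donors[which.min(n_px[donors])]
        assign_set[donor] <- s
      }
    }
  }
  lapply(list(train = "train", val = "val", test = "test"), function(s) {
    subset_labeled(data, data$patient_id %in%
                     names(assign_set)[assign_set == s])
  })
}

#' Lesion-level decision from per-pixel classifications
#'
#' A lesion is called malignant when the fraction of its pixels classified
#' malignant strictly exceeds the risk threshold (default 40%): such a
#' lesion shows clear evidence of malignant behavior. An empty pixel list
#' (segmentation found no lesion, typically a capture in non-optimal
#' conditions) yields status `reacquire`, asking the user for a new
#' acquisition.
#'
#' @param pixel_labels Character vector of per-pixel classes
#'   (`"benign"`/`"malignant"`); may be empty.
#' @param threshold Risk threshold in [0, 1] (default 0.40).
#' @param pixel_scores Optional per-pixel malignant scores, reported
#'   alongside (their mean is informative but does not drive the call).
#' @return A list of class `lesion_decision`: `status` (`ok`/`reacquire`),
#'   `lesion_class` (`benign`/`malignant`/`none`), `malignant_fraction`,
#'   `mean_malignant_score`, `n_psl_pixels`, `threshold`, plus the inputs.
#' @export
lesion_decision <- function(pixel_labels, threshold = 0.40,
                            pixel_scores = NULL) {
  if (threshold < 0 || threshold > 1)
    stop_contract("threshold must lie in [0, 1]")
  n <- length(pixel_labels)
  if (n == 0L) {
    return(structure(list(status = "reacquire", lesion_class = "none",
                          malignant_fraction = NA_real_,
                          mean_malignant_score = NA_real_,
                          n_psl_pixels = 0L, threshold = threshold,
                          pixel_labels = character(0),
                          pixel_scores = numeric(0)),
                     class = "lesion_decision"))
  }
  frac <- sum(pixel_labels == "malignant") / n
  structure(list(
    status = "ok",
    lesion_class = if (frac > threshold) "malignant" else "benign",
    malignant_fraction = frac,
    mean_malignant_score = if (is.null(pixel_scores)) NA_real_
                           else mean(pixel_scores),
    n_psl_pixels = n, threshold = threshold,
    pixel_labels = pixel_labels,
    pixel_scores = if (is.null(pixel_scores)) numeric(0) else pixel_scores),
    class = "lesion_decision")
}

#' @export
print.lesion_decision <- function(x, ...) {
  if (x$status == "reacquire") {
    cat("<lesion_decision> no lesion pixels found - reacquire\n")
  } else {
    cat(sprintf(
      "<lesion_decision> %s (malignant fraction %.2f %s threshold %.2f, %d pixels)\n",
      x$lesion_class, x$malignant_fraction,
      if (x$malignant_fraction > x$threshold) ">" else "<=", x$threshold,
      x$n_psl_pixels))
  }
  invisible(x)
}

#' Run the complete clinical-support framework on one raw capture
#'
#' Pre-processing (calibration, trimming, smoothing, normalization), SAM +
#' K-means lesion segmentation, supervised classification of the lesion
#' pixels only, and the lesion-level risk-threshold decision. If the
#' segmentation finds no lesion pixels the decision status is `reacquire`.
#'
#' @param raw Raw [hs_cube()].
#' @param refs [ref_frames()] for calibration.
#' @param lib [spectral_library()] for the segmentation stage.
#' @param model Trained `hsderm_model` for the classification stage.
#' @param pre_cfg A [preprocess_config()].
#' @param seg_cfg A [segmentation_config()].
#' @param threshold Risk threshold for the lesion-level call.
#' @return A `lesion_decision` with attributes `two_class_map` (the
#'   segmentation result) and `preprocessed` (the preprocessed cube).
#' @export
run_framework <- function(raw, refs, lib, model,
                          pre_cfg = preprocess_config(),
                          seg_cfg = segmentation_config(),
                          threshold = 0.40) {
  pre <- preprocess_chain(raw, refs, pre_cfg)
  if (!isTRUE(all.equal(pre$wavelengths_nm, lib$wavelengths_nm)))
    stop_contract("library wavelength grid does not match the preprocessed cube")
  map <- segment_psl(pre, lib, seg_cfg)
  psl_idx <- which(t(map$values == "psl"))  # row-major pixel index
  if (length(psl_idx) == 0L) {
    dec <- lesion_decision(character(0), threshold)
  } else {
    sp <- cube_spectra(pre)[psl_idx, , drop = FALSE]
    pr <- predict(model, sp)
    dec <- lesion_decision(pr$label, threshold, pixel_scores = pr$score)
  }
  attr(dec, "two_class_map") <- map
  attr(dec, "preprocessed") <- pre
  dec
}
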