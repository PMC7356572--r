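#' Labeled spectra set
#'
#' Pixel spectral signatures with their diagnostic class and provenance:
#' each row of `spectra` is one pixel, tagged with a class (`skin`,
#' `benign` or `malignant`), the patient it came from and the image it was
#' sampled in. Patient identifiers drive the patient-stratified split, so
#' no patient can leak across train/validation/test.
#'
#' @param spectra Numeric matrix, one spectrum per row.
#' @param class Character vector, one of `"skin"`, `"benign"`, `"malignant"`
#'   per row.
#' @param patient_id,image_id Identifiers per row.
#' @param wavelengths_nm Shared wavelength grid of all rows.
#' @return An object of class `labeled_spectra`.
#' @export
labeled_spectra <- function(spectra, class, patient_id, image_id,
                            wavelengths_nm) {
  spectra <- as.matrix(spectra)
  n <- nrow(spectra)
  class <- as.character(class)
  patient_id <- as.character(patient_id)
  image_id <- as.character(image_id)
  if (length(class) != n || length(patient_id) != n || length(image_id) != n)
    stop_contract("class/patient_id/image_id must have one entry per spectrum")
  bad <- setdiff(unique(class), .classes)
  if (length(bad))
    stop_format("unknown class label(s): ", paste(bad, collapse = ", "))
  if (ncol(spectra) != length(wavelengths_nm))
    stop_contract("spectra column count must match the wavelength grid")
  structure(list(spectra = spectra, class = class, patient_id = patient_id,
                 image_id = image_id,
                 wavelengths_nm = as.numeric(wavelengths_nm)),
            class = "labeled_spectra")
}

#' @export
print.labeled_spectra <- function(x, ...) {
  tab <- table(x$class)
  cat(sprintf("<labeled_spectra> %d spectra x %d bands, %d patients (%s)\n",
              nrow(x$spectra), ncol(x$spectra),
              length(unique(x$patient_id)),
              paste(names(tab), tab, sep = ": ", collapse = ", ")))
  invisible(x)
}

#' Subset a labeled spectra set by row index
#'
#' @param set A [labeled_spectra()].
#' @param idx Integer or logical row index.
#' @return A [labeled_spectra()] with the selected rows.
#' @export
subset_labeled <- function(set, idx) {
  labeled_spectra(set$spectra[idx, , drop = FALSE], set$class[idx],
                  set$patient_id[idx], set$image_id[idx], set$wavelengths_nm)
}

#' Concatenate labeled spectra sets sharing a wavelength grid
#'
#' @param ... [labeled_spectra()] objects.
#' @return A single [labeled_spectra()].
#' @export
bind_labeled <- function(...) {
  sets <- list(...)
  stopifnot(length(sets) >= 1L)
  wl <- sets[[1L]]$wavelengths_nm
  for (s in sets)
    if (!isTRUE(all.equal(s$wavelengths_nm, wl)))
      stop_contract("labeled sets must share one wavelength grid")
  labeled_spectra(do.call(rbind, lapply(sets, `[[`, "spectra")),
                  unlist(lapply(sets, `[[`, "class")),
                  unlist(lapply(sets, `[[`, "patient_id")),
                  unlist(lapply(sets, `[[`, "image_id")), wl)
}
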