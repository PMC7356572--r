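# Shared fixtures, all built in code at test time.

# tiny cube with per-pixel spectra given as a list of vectors (row-major)
tiny_cube <- function(spectra_list, rows, cols, wavelengths = NULL,
                      state = "preprocessed") {
  nb <- length(spectra_list[[1]])
  if (is.null(wavelengths)) wavelengths <- seq(450, 950, length.out = nb)
  v <- array(NA_real_, dim = c(rows, cols, nb))
  i <- 1L
  for (r in seq_len(rows)) for (c in seq_len(cols)) {
    v[r, c, ] <- spectra_list[[i]]
    i <- if (i == length(spectra_list)) 1L else i + 1L
  }
  hs_cube(v, wavelengths, state = state)
}

# cube with identical spectrum everywhere
flat_cube <- function(spectrum, rows = 3, cols = 3, state = "raw") {
  tiny_cube(list(spectrum), rows, cols, state = state)
}

# two-class linearly separable labeled set (benign vs malignant),
# patient ids split across the rows
separable_set <- function(n_per_class = 20, bands = 12, gap = 3,
                          noise = 0.3, seed = 42, patients = 4) {
  withr::with_seed(seed, {
    xb <- matrix(rnorm(n_per_class * bands, 0, noise), n_per_class)
    xm <- matrix(rnorm(n_per_class * bands, 0, noise), n_per_class)
    xm[, 1] <- xm[, 1] + gap
    x <- rbind(xb, xm)
    n <- nrow(x)
    labeled_spectra(x, rep(c("benign", "malignant"), each = n_per_class),
                    paste0("P", rep_len(seq_len(patients), n)),
                    paste0("I", rep_len(seq_len(patients), n)),
                    seq(450, 950, length.out = bands))
  })
}

# noisy, overlapping two-class set where model quality varies with
# hyperparameters (for GA tests); train/val patient-disjoint
noisy_split_set <- function(n_per_class = 30, bands = 8, seed = 7) {
  withr::with_seed(seed, {
    make_half <- function(pids) {
      n <- n_per_class
      xb <- matrix(rnorm(n * bands, 0, 1), n)
      xm <- matrix(rnorm(n * bands, 0, 1), n)
      xm[, 1:2] <- xm[, 1:2] + 1.2
      labeled_spectra(rbind(xb, xm),
                      rep(c("benign", "malignant"), each = n),
                      rep_len(pids, 2 * n), rep_len(pids, 2 * n),
                      seq(450, 950, length.out = bands))
    }
    list(train = make_half(c("PA", "PB")), val = make_half(c("PC", "PD")))
  })
}

# bare two-class map (internal constructor is not exported)
two_class_map_for_test <- function(values, method = "per_pixel") {
  structure(list(values = values, method = method, postprocessed = FALSE),
            class = "two_class_map")
}

# small synthetic labeled dataset shared by several tests (cached)
shared_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_dataset(n_patients = 12, seed = 3)
    cache
  }
})
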