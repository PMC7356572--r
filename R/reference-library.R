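#' Reference spectral library
#'
#' Named, class-tagged mean spectral signatures used by the SAM-based
#' segmentation stage. The canonical clinical configuration holds five
#' entries: three normal-skin cluster means (covering distinct skin
#' tones/types) plus the benign and the malignant class means, all on the
#' preprocessed ([0, 1] normalized) scale.
#'
#' @param name Character vector of unique entry names.
#' @param class Character vector, `"skin"`, `"benign"` or `"malignant"`.
#' @param spectra Numeric matrix, one spectrum per row.
#' @param wavelengths_nm Shared wavelength grid.
#' @return An object of class `spectral_library`.
#' @export
spectral_library <- function(name, class, spectra, wavelengths_nm) {
  spectra <- as.matrix(spectra)
  name <- as.character(name); class <- as.character(class)
  if (anyDuplicated(name))
    stop_format("duplicate library entry names: ",
                paste(unique(name[duplicated(name)]), collapse = ", "))
  bad <- setdiff(unique(class), .classes)
  if (length(bad))
    stop_format("unknown class label(s): ", paste(bad, collapse = ", "))
  if (nrow(spectra) != length(name) || length(class) != length(name))
    stop_contract("name, class and spectra rows must align")
  if (ncol(spectra) != length(wavelengths_nm))
    stop_contract("spectra column count must match the wavelength grid")
  structure(list(name = name, class = class, spectra = spectra,
                 wavelengths_nm = as.numeric(wavelengths_nm)),
            class = "spectral_library")
}

#' @export
print.spectral_library <- function(x, ...) {
  cat(sprintf("<spectral_library> %d entries x %d bands: %s\n",
              length(x$name), ncol(x$spectra),
              paste(x$name, " (", x$class, ")", sep = "", collapse = ", ")))
  invisible(x)
}

#' @export
length.spectral_library <- function(x) length(x$name)

# --- cluster-count selection indices ------------------------------------

# Calinski-Harabasz: between-cluster dispersion over within-cluster
# dispersion, scaled by (n - k)/(k - 1). Higher is better.
calinski_harabasz <- function(x, assign) {
  n <- nrow(x); k <- length(unique(assign))
  gm <- colMeans(x)
  w <- 0; b <- 0
  for (cl in unique(assign)) {
    xi <- x[assign == cl, , drop = FALSE]
    ci <- colMeans(xi)
    w <- w + sum(sweep(xi, 2L, ci)^2)
    b <- b + nrow(xi) * sum((ci - gm)^2)
  }
  (b / (k - 1)) / (w / (n - k))
}

# Davies-Bouldin: mean over clusters of the worst (s_i + s_j)/d_ij ratio,
# s_i the mean distance of members to their centroid. Lower is better.
davies_bouldin <- function(x, assign) {
  cls <- sort(unique(assign)); k <- length(cls)
  cent <- t(vapply(cls, function(cl) colMeans(x[assign == cl, , drop = FALSE]),
                   numeric(ncol(x))))
  s <- vapply(seq_len(k), function(i) {
    xi <- x[assign == cls[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(xi, 2L, cent[i, ])^2)))
  }, numeric(1))
  db <- vapply(seq_len(k), function(i) {
    r <- vapply(seq_len(k), function(j) {
      if (i == j) return(-Inf)
      (s[i] + s[j]) / sqrt(sum((cent[i, ] - cent[j, ])^2))
    }, numeric(1))
    max(r)
  }, numeric(1))
  mean(db)
}

mean_silhouette <- function(x, assign) {
  sil <- cluster::silhouette(assign, stats::dist(x))
  mean(sil[, "sil_width"])
}

# k-means++ seeding followed by stats::kmeans, best of `nstart` restarts.
# Deterministic under the caller's RNG state.
kmeanspp <- function(x, k, nstart = 10L, iter.max = 100L) {
  n <- nrow(x)
  best <- NULL
  for (r in seq_len(nstart)) {
    centers <- matrix(NA_real_, k, ncol(x))
    centers[1L, ] <- x[sample.int(n, 1L), ]
    d2 <- rowSums(sweep(x, 2L, centers[1L, ])^2)
    if (k > 1L) for (j in 2L:k) {
      if (all(d2 <= 0)) {
        centers[j, ] <- x[sample.int(n, 1L), ]
      } else {
        centers[j, ] <- x[sample.int(n, 1L, prob = d2 / sum(d2)), ]
        d2 <- pmin(d2, rowSums(sweep(x, 2L, centers[j, ])^2))
      }
    }
    centers <- centers[!duplicated(centers), , drop = FALSE]
    fit <- suppressWarnings(
      stats::kmeans(x, centers = centers, iter.max = iter.max))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  best
}

#' Select the number of normal-skin clusters with three internal indices
#'
#' Runs seeded K-means for every K in `k_range` and scores each partition
#' with the silhouette (maximize), Calinski-Harabasz (maximize) and
#' Davies-Bouldin (minimize) indices. Each index votes for its optimal K;
#' the consensus is the most frequent vote, with ties resolved toward the
#' smallest K.
#'
#' @param data Numeric matrix of spectra (rows = samples).
#' @param k_range Integer vector of candidate cluster counts (all >= 2).
#' @param seed Integer seed controlling the K-means restarts.
#' @return A list of class `k_selection`: `per_method` (named integer vector
#'   of optimal K per index), `consensus`, and `index_values` (method x K
#'   matrix of raw index values).
#' @export
evaluate_k <- function(data, k_range = 2:7, seed = 1L) {
  data <- as.matrix(data)
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 2L) stop_contract("k_range minimum must be >= 2")
  if (nrow(data) <= max(k_range))
    stop_contract("need more rows than the largest K")
  if (all(apply(data, 2L, function(col) diff(range(col)) == 0)) ||
      nrow(unique(data)) == 1L)
    stop_contract("degenerate data: all rows identical")
  idx <- matrix(NA_real_, nrow = 3L, ncol = length(k_range),
                dimnames = list(c("silhouette", "calinski_harabasz",
                                  "davies_bouldin"), k_range))
  with_seed(seed, {
    for (j in seq_along(k_range)) {
      fit <- kmeanspp(data, k_range[j])
      a <- fit$cluster
      idx["silhouette", j] <- mean_silhouette(data, a)
      idx["calinski_harabasz", j] <- calinski_harabasz(data, a)
      idx["davies_bouldin", j] <- davies_bouldin(data, a)
    }
  })
  per_method <- c(
    silhouette = k_range[which.max(idx["silhouette", ])],
    calinski_harabasz = k_range[which.max(idx["calinski_harabasz", ])],
    davies_bouldin = k_range[which.min(idx["davies_bouldin", ])]
  )
  votes <- table(per_method)
  winners <- as.integer(names(votes)[votes == max(votes)])
  structure(list(per_method = per_method, consensus = min(winners),
                 index_values = idx), class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  cat(sprintf("<k_selection> consensus K = %d (%s)\n", x$consensus,
              paste(names(x$per_method), x$per_method, sep = "=",
                    collapse = ", ")))
  invisible(x)
}

#' Build the reference spectral library from labeled training data
#'
#' Lesion entries are the per-class means of the labeled benign and
#' malignant spectra. Normal skin is more heterogeneous (skin tones), so
#' its labeled spectra are partitioned into `k_skin` groups with seeded
#' K-means and each cluster centroid becomes one skin entry, yielding
#' `k_skin + 2` entries (five in the canonical `k_skin = 3` configuration).
#'
#' @param train A [labeled_spectra()] containing all three classes.
#' @param k_skin Number of normal-skin clusters (>= 1).
#' @param seed Integer seed for the skin K-means.
#' @return A [spectral_library()] with `k_skin + 2` entries.
#' @export
build_reference_library <- function(train, k_skin = 3L, seed = 1L) {
  stopifnot(inherits(train, "labeled_spectra"))
  k_skin <- as.integer(k_skin)
  if (k_skin < 1L) stop_contract("k_skin must be >= 1")
  miss <- setdiff(.classes, unique(train$class))
  if (length(miss))
    stop_contract("training set lacks class(es): ", paste(miss, collapse = ", "))
  skin <- train$spectra[train$class == "skin", , drop = FALSE]
  if (k_skin == 1L) {
    skin_centers <- matrix(colMeans(skin), nrow = 1L)
  } else {
    if (nrow(skin) < k_skin)
      stop_contract("fewer skin spectra than k_skin")
    fit <- with_seed(seed, kmeanspp(skin, k_skin))
    skin_centers <- fit$centers
  }
  # canonical order: ascending mean reflectance
  skin_centers <- skin_centers[order(rowMeans(skin_centers)), , drop = FALSE]
  spectra <- rbind(
    skin_centers,
    colMeans(train$spectra[train$class == "benign", , drop = FALSE]),
    colMeans(train$spectra[train$class == "malignant", , drop = FALSE])
  )
  spectral_library(
    name = c(paste0("skin_", seq_len(k_skin)), "benign", "malignant"),
    class = c(rep("skin", k_skin), "benign", "malignant"),
    spectra = spectra,
    wavelengths_nm = train$wavelengths_nm
  )
}
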