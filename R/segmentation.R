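# Unsupervised two-class lesion segmentation: K-means over the pixel
# spectra, SAM comparison of clusters against the reference library (per
# centroid or per pixel), then morphological cleanup of the lesion layer.

#' Segmentation configuration
#'
#' @param K Number of K-means clusters (default 7, the configuration that
#'   performed best with the per-pixel assignment on clinical validation).
#' @param method Cluster-to-class assignment: `"per_pixel"` (default) sums
#'   the SAM of every member pixel against each library entry;
#'   `"per_centroid"` compares only the cluster centroid.
#' @param selem_size Odd side of the square structuring element for the
#'   morphological closing (default 3).
#' @param min_component_px Minimum 8-connected lesion component size kept
#'   after closing (default 4; smaller islands are dropped).
#' @param seed Integer seed for the K-means restarts.
#' @return A list of class `segmentation_config`.
#' @export
segmentation_config <- function(K = 7L, method = c("per_pixel", "per_centroid"),
                                selem_size = 3L, min_component_px = 4L,
                                seed = 1L) {
  method <- match.arg(method)
  K <- as.integer(K); selem_size <- as.integer(selem_size)
  if (K < 2L) stop_contract("K must be >= 2")
  if (selem_size < 1L || selem_size %% 2L == 0L)
    stop_contract("selem_size must be odd")
  structure(list(K = K, method = method, selem_size = selem_size,
                 min_component_px = as.integer(min_component_px),
                 seed = as.integer(seed)), class = "segmentation_config")
}

#' Cluster a cube's pixel spectra with seeded K-means
#'
#' Pixels are clustered in spectral space (k-means++ seeding, 10 restarts,
#' Euclidean distance). Centroids are returned in canonical order
#' (ascending mean reflectance) so cluster indices are reproducible; the
#' indices themselves carry no class meaning.
#'
#' @param cube A preprocessed [hs_cube()].
#' @param K Number of clusters (at most the pixel count).
#' @param seed Integer seed.
#' @return A list of class `cluster_map`: `assignments` (`rows x cols`
#'   integer matrix in `1..K`), `centroids` (`K x bands`), `K`, `seed`.
#' @export
kmeans_cluster <- function(cube, K = 7L, seed = 1L) {
  stopifnot(inherits(cube, "hs_cube"))
  d <- dim(cube$values)
  K <- as.integer(K)
  if (K > d[1L] * d[2L]) stop_contract("K exceeds the pixel count")
  sp <- cube_spectra(cube)
  if (K == 1L) {
    centroids <- matrix(colMeans(sp), 1L)
    assign <- rep(1L, nrow(sp))
  } else {
    fit <- with_seed(seed, kmeanspp(sp, K))
    ord <- order(rowMeans(fit$centers))
    centroids <- fit$centers[ord, , drop = FALSE]
    assign <- match(fit$cluster, ord)
  }
  dimnames(centroids) <- NULL
  structure(list(assignments = pixel_field(assign, d[1L], d[2L]),
                 centroids = centroids, K = nrow(centroids),
                 seed = as.integer(seed)),
            class = "cluster_map")
}

#' @export
print.cluster_map <- function(x, ...) {
  cat(sprintf("<cluster_map> %d x %d px, K = %d\n",
              nrow(x$assignments), ncol(x$assignments), x$K))
  invisible(x)
}

two_class_map <- function(values, method, postprocessed = FALSE) {
  structure(list(values = values, method = method,
                 postprocessed = postprocessed), class = "two_class_map")
}

#' @export
print.two_class_map <- function(x, ...) {
  cat(sprintf("<two_class_map> %d x %d px, %d psl pixels (%s%s)\n",
              nrow(x$values), ncol(x$values), sum(x$values == "psl"),
              x$method, if (x$postprocessed) ", postprocessed" else ""))
  invisible(x)
}

# class of library entry -> two-class label
entry_two_class <- function(cls) ifelse(cls == "skin", "skin", "psl")

# resolve the winning library entry with ties broken toward skin
argmin_toward_skin <- function(scores, lib_class) {
  best <- min(scores)
  cand <- which(scores <= best + 1e-12)
  skin_cand <- cand[lib_class[cand] == "skin"]
  if (length(skin_cand)) skin_cand[1L] else cand[1L]
}

#' Assign clusters to skin/lesion by SAM of their centroids
#'
#' Each cluster centroid is compared against every reference library entry;
#' the cluster takes the two-class label (skin vs. lesion) of the
#' SAM-nearest entry, ties broken toward skin.
#'
#' @param clusters A `cluster_map` from [kmeans_cluster()].
#' @param lib A [spectral_library()] on the same wavelength grid.
#' @return A `two_class_map` (`values` is a `rows x cols` character matrix
#'   of `"skin"`/`"psl"`).
#' @export
assign_per_centroid <- function(clusters, lib) {
  stopifnot(inherits(clusters, "cluster_map"),
            inherits(lib, "spectral_library"))
  if (length(lib) == 0L) stop_contract("reference library is empty")
  if (ncol(clusters$centroids) != ncol(lib$spectra))
    stop_contract("centroids and library are on different band grids")
  cls_label <- vapply(seq_len(clusters$K), function(c) {
    ang <- vapply(seq_len(length(lib)), function(r)
      sam_angle(clusters$centroids[c, ], lib$spectra[r, ]), numeric(1))
    entry_two_class(lib$class[argmin_toward_skin(ang, lib$class)])
  }, character(1))
  vals <- matrix(cls_label[clusters$assignments],
                 nrow(clusters$assignments), ncol(clusters$assignments))
  two_class_map(vals, "per_centroid")
}

#' Assign clusters to skin/lesion by summed per-pixel SAM
#'
#' For each cluster and each library entry, sums the SAM angle of every
#' member pixel against that entry; the cluster takes the two-class label
#' of the entry with the smallest sum (ties toward skin). Aggregation is
#' per entry, not per class, so classes with more entries gain no
#' advantage. Empty clusters are skipped.
#'
#' @param cube The preprocessed [hs_cube()] the clusters came from.
#' @param clusters A `cluster_map` from [kmeans_cluster()].
#' @param lib A [spectral_library()].
#' @return A `two_class_map`.
#' @export
assign_per_pixel <- function(cube, clusters, lib) {
  stopifnot(inherits(cube, "hs_cube"), inherits(clusters, "cluster_map"),
            inherits(lib, "spectral_library"))
  if (length(lib) == 0L) stop_contract("reference library is empty")
  sp <- cube_spectra(cube)
  if (ncol(sp) != ncol(lib$spectra))
    stop_contract("cube and library are on different band grids")
  assign_vec <- as.vector(t(clusters$assignments))  # row-major like sp
  # angles of every pixel against every entry
  ang <- vapply(seq_len(length(lib)), function(r)
    sam_angles_matrix(sp, lib$spectra[r, ]), numeric(nrow(sp)))
  cls_label <- rep(NA_character_, clusters$K)
  for (c in seq_len(clusters$K)) {
    members <- assign_vec == c
    if (!any(members)) next
    sums <- colSums(ang[members, , drop = FALSE], na.rm = TRUE)
    cls_label[c] <- entry_two_class(
      lib$class[argmin_toward_skin(sums, lib$class)])
  }
  vals <- matrix(cls_label[clusters$assignments],
                 nrow(clusters$assignments), ncol(clusters$assignments))
  two_class_map(vals, "per_pixel")
}

#' Morphological cleanup of a two-class map
#'
#' Applies a binary closing (dilation then erosion with a square
#' `selem_size` element) to the lesion layer, then removes 8-connected
#' lesion components smaller than `min_component_px` — small isolated
#' regions that closing alone cannot eliminate.
#'
#' @param map A `two_class_map` (not yet postprocessed).
#' @param cfg A [segmentation_config()].
#' @return The postprocessed `two_class_map`.
#' @export
postprocess_map <- function(map, cfg = segmentation_config()) {
  stopifnot(inherits(map, "two_class_map"))
  if (isTRUE(map$postprocessed))
    stop_contract("map is already postprocessed")
  psl <- map$values == "psl"
  psl <- binary_close(psl, cfg$selem_size)
  psl <- remove_small_components(psl, cfg$min_component_px)
  vals <- ifelse(psl, "psl", "skin")
  out <- two_class_map(vals, map$method, postprocessed = TRUE)
  out
}

#' Segment lesion pixels in a preprocessed cube
#'
#' The full unsupervised stage: seeded K-means clustering, SAM-based
#' cluster-to-class assignment against the reference library, and
#' morphological postprocessing. Zero detected lesion pixels is a legal
#' outcome (the downstream framework then requests reacquisition).
#'
#' @param cube A preprocessed [hs_cube()].
#' @param lib A [spectral_library()] with at least one skin and one lesion
#'   entry.
#' @param cfg A [segmentation_config()].
#' @return A `two_class_map` with attribute `n_psl_pixels`.
#' @export
segment_psl <- function(cube, lib, cfg = segmentation_config()) {
  clusters <- kmeans_cluster(cube, cfg$K, cfg$seed)
  map <- switch(cfg$method,
    per_centroid = assign_per_centroid(clusters, lib),
    per_pixel = assign_per_pixel(cube, clusters, lib))
  map <- postprocess_map(map, cfg)
  attr(map, "n_psl_pixels") <- sum(map$values == "psl")
  attr(map, "cluster_map") <- clusters
  map
}
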