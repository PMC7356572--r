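# On-disk artifacts. Cubes travel as ENVI header/binary pairs (BSQ,
# little-endian, IEEE-754 32-bit float, wavelengths in nm); masks as 8-bit
# single-channel PNG (0 = skin/background, nonzero = lesion); spectral
# libraries and labeled sets as CSV.

envi_data_path <- function(hdr_path) sub("\\.hdr$", ".raw", hdr_path)

#' Write a hyperspectral cube as an ENVI header/binary pair
#'
#' The header carries the standard ENVI fields (`samples`, `lines`, `bands`,
#' `data type`, `interleave`, `byte order`, `wavelength`) plus a custom
#' `state` key recording the processing state, so round-trips preserve it.
#' Data are stored band-sequential (BSQ), little-endian 32-bit float, pixels
#' in row-major order within each band.
#'
#' @param cube An [hs_cube()].
#' @param path Path of the header file (`.hdr` appended if absent); the
#'   binary companion is written next to it with extension `.raw`.
#' @return The header path, invisibly.
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "hs_cube"))
  if (!grepl("\\.hdr$", path)) path <- paste0(path, ".hdr")
  d <- dim(cube$values)
  wl <- paste(format(cube$wavelengths_nm, trim = TRUE, digits = 10),
              collapse = ", ")
  hdr <- c(
    "ENVI",
    "description = { hsderm hyperspectral cube }",
    paste0("samples = ", d[2L]),
    paste0("lines = ", d[1L]),
    paste0("bands = ", d[3L]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 4",
    "interleave = bsq",
    "byte order = 0",
    paste0("state = ", cube$state),
    "wavelength units = Nanometers",
    paste0("wavelength = { ", wl, " }")
  )
  ok <- tryCatch({
    writeLines(hdr, path)
    con <- file(envi_data_path(path), "wb")
    on.exit(close(con), add = TRUE)
    # BSQ: per band, row-major pixel order
    v <- aperm(cube$values, c(2L, 1L, 3L))  # col varies fastest in R fold
    writeBin(as.vector(v, mode = "numeric"), con, size = 4L,
             endian = "little")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop_io("cannot write ENVI pair at '", path, "': ",
                           conditionMessage(ok))
  invisible(path)
}

parse_envi_header <- function(hdr_path) {
  lines <- readLines(hdr_path, warn = FALSE)
  fields <- list()
  # re-join multi-line { ... } values before key = value parsing
  buf <- character(0); open <- FALSE; cur <- ""
  for (ln in lines) {
    if (!open) cur <- ln else cur <- paste(cur, ln)
    open <- grepl("\\{", cur) && !grepl("\\}", cur)
    if (!open) { buf <- c(buf, cur); cur <- "" }
  }
  for (ln in buf) {
    if (!grepl("=", ln)) next
    key <- tolower(trimws(sub("=.*$", "", ln)))
    val <- trimws(sub("^[^=]*=", "", ln))
    fields[[key]] <- val
  }
  fields
}

#' Read a hyperspectral cube from an ENVI header/binary pair
#'
#' @param path Path to the `.hdr` header (a path without the extension is
#'   also accepted). The binary companion is looked up as `.raw`, then as
#'   the header path with its extension stripped.
#' @return An [hs_cube()] with wavelengths taken from the header and state
#'   from the custom `state` key (`raw` when absent).
#' @export
read_cube <- function(path) {
  if (!grepl("\\.hdr$", path)) path <- paste0(path, ".hdr")
  if (!file.exists(path)) stop_io("ENVI header not found: '", path, "'")
  f <- parse_envi_header(path)
  need <- c("samples", "lines", "bands", "data type", "interleave")
  miss <- setdiff(need, names(f))
  if (length(miss))
    stop_format("ENVI header missing field(s): ", paste(miss, collapse = ", "))
  samples <- as.integer(f[["samples"]]); lines_n <- as.integer(f[["lines"]])
  bands <- as.integer(f[["bands"]])
  if (tolower(f[["interleave"]]) != "bsq")
    stop_format("only BSQ interleave is supported, got '", f[["interleave"]], "'")
  if (as.integer(f[["data type"]]) != 4L)
    stop_format("only data type 4 (32-bit float) is supported")
  if (is.null(f[["wavelength"]]))
    stop_format("ENVI header lacks a wavelength list")
  wl <- as.numeric(strsplit(gsub("[{}]", "", f[["wavelength"]]), ",")[[1]])
  wl <- wl[!is.na(wl)]
  if (length(wl) != bands)
    stop_format("wavelength list length (", length(wl),
                ") does not match bands (", bands, ")")
  data_path <- envi_data_path(path)
  if (!file.exists(data_path)) data_path <- sub("\\.hdr$", "", path)
  if (!file.exists(data_path))
    stop_io("ENVI binary companion of '", path, "' not found")
  n <- samples * lines_n * bands
  endian <- if (!is.null(f[["byte order"]]) &&
                as.integer(f[["byte order"]]) == 1L) "big" else "little"
  con <- file(data_path, "rb")
  on.exit(close(con), add = TRUE)
  v <- readBin(con, what = "numeric", n = n, size = 4L, endian = endian)
  if (length(v) != n)
    stop_format("ENVI binary holds ", length(v), " values, expected ", n)
  arr <- aperm(array(v, dim = c(samples, lines_n, bands)), c(2L, 1L, 3L))
  state <- if (!is.null(f[["state"]]) &&
               f[["state"]] %in% c("raw", "calibrated", "preprocessed"))
    f[["state"]] else "raw"
  hs_cube(arr, wl, state = state)
}

#' Read and write binary lesion masks as 8-bit single-channel PNG
#'
#' Zero pixels are background (normal skin), any nonzero value is lesion.
#'
#' @param path PNG file path.
#' @return `read_mask`: a logical `rows x cols` matrix (`TRUE` = lesion).
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop_io("mask PNG not found: '", path, "'")
  img <- png::readPNG(path)
  if (length(dim(img)) != 2L)
    stop_format("mask must be a single-channel PNG, got ",
                dim(img)[3L], " channels")
  img > 0
}

#' @rdname read_mask
#' @param mask Logical matrix (`TRUE` = lesion pixel).
#' @return `write_mask`: the path, invisibly.
#' @export
write_mask <- function(mask, path) {
  if (!is.matrix(mask)) stop_contract("mask must be a matrix")
  ok <- tryCatch({
    png::writePNG(matrix(as.numeric(mask > 0), nrow(mask), ncol(mask)), path)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop_io("cannot write mask PNG: ", conditionMessage(ok))
  invisible(path)
}

#' Read and write reference spectral libraries as CSV
#'
#' The CSV layout is `name, class, <one column per wavelength>` with
#' wavelength column headers carrying the band centers in nm (any `wl_`/`b`
#' prefix is stripped before parsing).
#'
#' @param path CSV file path.
#' @return `read_library`: a [spectral_library()].
#' @export
read_library <- function(path) {
  if (!file.exists(path)) stop_io("library CSV not found: '", path, "'")
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop_format("library CSV has no entries")
  if (!all(c("name", "class") %in% names(df)))
    stop_format("library CSV must have 'name' and 'class' columns")
  wl_cols <- setdiff(names(df), c("name", "class"))
  wl <- as.numeric(sub("^(wl_?|b)", "", wl_cols))
  if (anyNA(wl)) stop_format("cannot parse wavelength column headers")
  spectra <- as.matrix(df[, wl_cols, drop = FALSE])
  dimnames(spectra) <- NULL
  spectral_library(name = df$name, class = df$class, spectra = spectra,
                   wavelengths_nm = wl)
}

#' @rdname read_library
#' @param lib A [spectral_library()].
#' @return `write_library`: the path, invisibly.
#' @export
write_library <- function(lib, path) {
  stopifnot(inherits(lib, "spectral_library"))
  df <- data.frame(name = lib$name, class = lib$class,
                   stringsAsFactors = FALSE)
  sp <- as.data.frame(lib$spectra)
  names(sp) <- format(lib$wavelengths_nm, trim = TRUE, digits = 10)
  utils::write.csv(cbind(df, sp), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write labeled spectra sets as CSV
#'
#' Layout: `patient_id, image_id, class, <one column per wavelength>`.
#'
#' @param path CSV file path.
#' @return `read_labeled_spectra`: a [labeled_spectra()].
#' @export
read_labeled_spectra <- function(path) {
  if (!file.exists(path)) stop_io("labeled spectra CSV not found: '", path, "'")
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("patient_id", "image_id", "class")
  if (!all(need %in% names(df)))
    stop_format("labeled spectra CSV must have columns ",
                paste(need, collapse = ", "))
  wl_cols <- setdiff(names(df), need)
  wl <- as.numeric(sub("^(wl_?|b)", "", wl_cols))
  if (anyNA(wl)) stop_format("cannot parse wavelength column headers")
  spectra <- as.matrix(df[, wl_cols, drop = FALSE])
  dimnames(spectra) <- NULL
  labeled_spectra(spectra = spectra, class = df$class,
                  patient_id = df$patient_id, image_id = df$image_id,
                  wavelengths_nm = wl)
}

#' @rdname read_labeled_spectra
#' @param set A [labeled_spectra()].
#' @return `write_labeled_spectra`: the path, invisibly.
#' @export
write_labeled_spectra <- function(set, path) {
  stopifnot(inherits(set, "labeled_spectra"))
  df <- data.frame(patient_id = set$patient_id, image_id = set$image_id,
                   class = set$class, stringsAsFactors = FALSE)
  sp <- as.data.frame(set$spectra)
  names(sp) <- format(set$wavelengths_nm, trim = TRUE, digits = 10)
  utils::write.csv(cbind(df, sp), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
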