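#' Readers and writers for curves, cubes, masks and run manifests
#'
#' Spectral curves and camera responses travel as comma-separated CSV
#' with a mandatory header and '.' decimals; hyperspectral cubes as ENVI
#' (band-sequential float32 binary plus an ASCII `.hdr` carrying the
#' wavelength list); masks as 8-bit PNG (0 = background, 255 = pepper);
#' run manifests as JSON. All writers are deterministic given identical
#' inputs, and all readers validate their invariants with actionable
#' messages.
#'
#' @name io
NULL

#' Read a spectral curve from CSV
#'
#' Expects columns `wavelength_nm` and a value column (first non-
#' wavelength column). Rows are sorted by wavelength; duplicate or
#' non-finite wavelengths and values outside `[0, 1.5]` are rejected with
#' the offending line number.
#'
#' @param path CSV file path.
#' @return A [spectral_curve()].
#' @export
read_spectral_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) < 1L) stop(sprintf("%s: no data rows", path), call. = FALSE)
  wcol <- grep("wavelength", names(df), ignore.case = TRUE)[1]
  if (is.na(wcol)) {
    stop(sprintf("%s: no wavelength column in header", path), call. = FALSE)
  }
  vcol <- setdiff(seq_along(df), wcol)[1]
  wl <- suppressWarnings(as.numeric(df[[wcol]]))
  v <- suppressWarnings(as.numeric(df[[vcol]]))
  bad <- which(!is.finite(wl) | !is.finite(v))
  if (length(bad)) {
    stop(sprintf("%s: malformed row at line %d", path, bad[1] + 1L),
         call. = FALSE)
  }
  out_of_range <- which(v < 0 | v > 1.5)
  if (length(out_of_range)) {
    stop(sprintf("%s: value outside [0, 1.5] at line %d", path,
                 out_of_range[1] + 1L), call. = FALSE)
  }
  ord <- order(wl)
  wl <- wl[ord]; v <- v[ord]
  dup <- which(diff(wl) <= 0)
  if (length(dup)) {
    stop(sprintf("%s: non-increasing wavelength at line %d (after sorting)",
                 path, dup[1] + 1L), call. = FALSE)
  }
  spectral_curve(wl, v)
}

#' Write a spectral curve (or polarized response) to CSV
#'
#' A `spectral_curve` writes `wavelength_nm, value`; a
#' `spectral_response` writes `wavelength_nm, T_s, T_p, T_unpolarized`.
#'
#' @param curve Curve or response tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectral_csv <- function(curve, path) {
  if (inherits(curve, "spectral_response")) {
    df <- data.frame(wavelength_nm = curve$wavelength,
                     T_s = curve$T_s, T_p = curve$T_p,
                     T_unpolarized = (curve$T_s + curve$T_p) / 2)
  } else {
    df <- data.frame(wavelength_nm = curve$wavelength, value = curve$value)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a 3-channel camera spectral response from CSV
#'
#' Expects columns `wavelength_nm, R, G, B` (any order, case-insensitive
#' channel names).
#'
#' @param path CSV file path.
#' @return A `camera_csr` tibble.
#' @export
read_csr_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  nm <- tolower(names(df))
  wcol <- grep("wavelength", nm)[1]
  get_channel <- function(ch) {
    i <- which(nm == ch)[1]
    if (is.na(i)) stop(sprintf("%s: missing channel column '%s'", path, ch),
                       call. = FALSE)
    v <- as.numeric(df[[i]])
    if (any(!is.finite(v) | v < 0)) {
      stop(sprintf("%s: channel '%s' has negative or non-finite values",
                   path, ch), call. = FALSE)
    }
    v
  }
  wl <- as.numeric(df[[wcol]])
  ord <- order(wl)
  out <- tibble::tibble(wavelength = wl[ord], R = get_channel("r")[ord],
                        G = get_channel("g")[ord], B = get_channel("b")[ord])
  validate_grid(out$wavelength)
  class(out) <- c("camera_csr", class(out))
  out
}

#' Write a camera spectral response to CSV
#' @param csr A `camera_csr` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_csr_csv <- function(csr, path) {
  df <- data.frame(wavelength_nm = csr$wavelength,
                   R = csr$R, G = csr$G, B = csr$B)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a hyperspectral cube as an ENVI image
#'
#' Band-sequential float32 with byte order 0 and an ASCII header file
#' (`<path>.hdr`) carrying the band wavelengths.
#'
#' @param scene A scene (or any list with `cube` and `wavelengths`).
#' @param path Output path for the binary file (header gets `.hdr`
#'   appended).
#' @return `path`, invisibly.
#' @export
write_envi <- function(scene, path) {
  cube <- scene$cube
  H <- dim(cube)[1]; W <- dim(cube)[2]; B <- dim(cube)[3]
  hdr <- c(
    "ENVI",
    "description = {synthetic hyperspectral scene}",
    sprintf("samples = %d", W),
    sprintf("lines = %d", H),
    sprintf("bands = %d", B),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 4",
    "interleave = bsq",
    "byte order = 0",
    "wavelength units = Nanometers",
    sprintf("wavelength = {%s}",
            paste(format(scene$wavelengths, trim = TRUE), collapse = ", "))
  )
  writeLines(hdr, paste0(path, ".hdr"))
  con <- file(path, "wb")
  on.exit(close(con))
  # BSQ: band-major, within band row-major lines of samples
  for (b in seq_len(B)) {
    writeBin(as.numeric(t(cube[, , b])), con, size = 4L, endian = "little")
  }
  invisible(path)
}

parse_envi_header <- function(hdr_path) {
  txt <- paste(readLines(hdr_path, warn = FALSE), collapse = "\n")
  get_num <- function(key) {
    m <- regmatches(txt, regexpr(paste0(key, "\\s*=\\s*[0-9]+"), txt))
    if (!length(m)) stop(sprintf("%s: missing '%s'", hdr_path, key),
                         call. = FALSE)
    as.integer(sub(".*=\\s*", "", m))
  }
  wl_m <- regmatches(txt, regexpr("wavelength\\s*=\\s*\\{[^}]*\\}", txt))
  if (!length(wl_m)) {
    stop(sprintf("%s: missing wavelength list", hdr_path), call. = FALSE)
  }
  wl <- as.numeric(strsplit(gsub(".*\\{|\\}", "", wl_m), ",")[[1]])
  list(samples = get_num("samples"), lines = get_num("lines"),
       bands = get_num("bands"), data_type = get_num("data type"),
       wavelengths = wl)
}

#' Read an ENVI hyperspectral image
#'
#' Supports the subset written by [write_envi()]: BSQ interleave, float32,
#' byte order 0.
#'
#' @param path Binary file path (header expected at `<path>.hdr`).
#' @return List with `cube` (H x W x B array) and `wavelengths`.
#' @export
read_envi <- function(path) {
  hdr <- parse_envi_header(paste0(path, ".hdr"))
  if (hdr$data_type != 4L) {
    stop(sprintf("%s: unsupported ENVI data type %d (expected 4 = float32)",
                 path, hdr$data_type), call. = FALSE)
  }
  if (length(hdr$wavelengths) != hdr$bands) {
    stop(sprintf("%s: wavelength list length does not match band count",
                 path), call. = FALSE)
  }
  n <- hdr$samples * hdr$lines * hdr$bands
  raw <- readBin(path, numeric(), n = n, size = 4L, endian = "little")
  if (length(raw) != n) {
    stop(sprintf("%s: truncated ENVI file", path), call. = FALSE)
  }
  cube <- array(0, dim = c(hdr$lines, hdr$samples, hdr$bands))
  per_band <- hdr$samples * hdr$lines
  for (b in seq_len(hdr$bands)) {
    cube[, , b] <- t(matrix(raw[((b - 1) * per_band + 1):(b * per_band)],
                            hdr$samples, hdr$lines))
  }
  structure(list(cube = cube, mask = NULL, wavelengths = hdr$wavelengths,
                 spec = NULL),
            class = "hyperspectral_scene")
}

#' Write a binary mask as 8-bit PNG (0 = background, 255 = pepper)
#' @param mask H x W integer matrix with values in `{0, 1}`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Read a binary mask PNG written by [write_mask_png()]
#' @param path PNG path.
#' @return H x W integer matrix (1 = pepper).
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  matrix(as.integer(img > 0.5), nrow(img), ncol(img))
}

#' Write an RGB image as PNG
#' @param image H x W x 3 array in `[0, 1]`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_rgb_png <- function(image, path) {
  png::writePNG(unclass(image), path)
  invisible(path)
}

#' Write a reproducibility manifest for a run
#'
#' Records the command, parameter map, master seed, md5 of input files,
#' and the package version. Timestamps are deliberately excluded so that
#' rerunning with the same inputs yields byte-identical manifests.
#'
#' @param command Stage name.
#' @param params Named list of parameters.
#' @param seed Master seed.
#' @param inputs Character vector of input file paths to hash.
#' @param path Output JSON path.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(command, params, seed, inputs = character(),
                           path) {
  hashes <- if (length(inputs)) {
    h <- as.list(tools::md5sum(inputs))
    names(h) <- basename(inputs)
    h
  } else NULL
  manifest <- list(command = command,
                   parameters = params,
                   seed = seed,
                   input_md5 = hashes,
                   tool = "widefilm",
                   version = tryCatch(
                     as.character(utils::packageVersion("widefilm")),
                     error = function(e) "dev"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(manifest)
}
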