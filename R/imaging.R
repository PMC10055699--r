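#' Hyperspectral-to-RGB imaging through a filter and a camera response
#'
#' The optical system is modelled as two diagonal spectral weights applied
#' to each pixel spectrum: the filter transmittance T(lambda) and the
#' three camera-spectral-response (CSR) channels. The synthesized channel
#' value is
#'   RGB_c(x, y) = exposure * sum_l cube(x, y, l) T(l) CSR_c(l) dl
#' with trapezoidal band weights, clipped to `[0, 1]` after exposure.
#' Filter and CSR commute (both are diagonal), and the map is linear in
#' the cube and in the filter before clipping.
#'
#' @name imaging
NULL

#' Three-channel Gaussian-like camera spectral response
#'
#' A smooth synthetic stand-in for a machine-vision RGB sensor's response
#' (peaks near 460/540/600 nm); supply a measured CSR via
#' [read_csr_csv()] to override.
#'
#' @param grid Wavelength vector, nm.
#' @return Tibble of class `camera_csr` with columns `wavelength`, `R`,
#'   `G`, `B`.
#' @export
default_csr <- function(grid = default_grid()) {
  gauss <- function(c0, s) exp(-((grid - c0) / s)^2)
  out <- tibble::tibble(wavelength = as.numeric(grid),
                        R = gauss(600, 45), G = gauss(540, 40),
                        B = gauss(460, 35))
  class(out) <- c("camera_csr", class(out))
  out
}

resample_csr <- function(csr, grid) {
  if (nrow(csr) == length(grid) &&
      max(abs(csr$wavelength - grid)) <= 1e-9) return(csr)
  out <- tibble::tibble(
    wavelength = as.numeric(grid),
    R = resample_curve(spectral_curve(csr$wavelength, csr$R), grid)$value,
    G = resample_curve(spectral_curve(csr$wavelength, csr$G), grid)$value,
    B = resample_curve(spectral_curve(csr$wavelength, csr$B), grid)$value)
  class(out) <- c("camera_csr", class(out))
  out
}

# trapezoidal integration weights for a (possibly irregular) grid
trapezoid_weights <- function(grid) {
  n <- length(grid)
  if (n == 1L) return(1)
  w <- numeric(n)
  dg <- diff(grid)
  w[1] <- dg[1] / 2
  w[n] <- dg[n - 1] / 2
  if (n > 2L) w[2:(n - 1)] <- (dg[-(n - 1)] + dg[-1]) / 2
  w
}

# raw (unexposed, unclipped) channel integrals: returns H x W x 3 array
integrate_channels <- function(cube, wavelengths, filter_values, csr) {
  B <- dim(cube)[3]
  stopifnot(length(wavelengths) == B, length(filter_values) == B)
  w <- trapezoid_weights(wavelengths)
  Wmat <- cbind(R = csr$R, G = csr$G, B = csr$B) * filter_values * w
  X <- matrix(cube, ncol = B)
  out <- X %*% Wmat
  array(out, dim = c(dim(cube)[1], dim(cube)[2], 3L))
}

#' Exposure that maps the no-filter image's 99th percentile to 0.95
#'
#' Computed once from the unfiltered integrals so that all curve swaps in
#' one evaluation share the same radiometric scale and remain comparable.
#'
#' @param cubes A scene, list of scenes, or H x W x B array(s).
#' @param csr Camera response (see [default_csr()]).
#' @return Scalar exposure.
#' @export
auto_exposure <- function(cubes, csr = NULL) {
  scenes <- normalize_scenes(cubes)
  vals <- unlist(lapply(scenes, function(sc) {
    cs <- if (is.null(csr)) default_csr(sc$wavelengths) else {
      resample_csr(csr, sc$wavelengths)
    }
    raw <- integrate_channels(sc$cube, sc$wavelengths,
                              rep(1, length(sc$wavelengths)), cs)
    as.numeric(raw)
  }))
  q <- stats::quantile(vals, 0.99, names = FALSE)
  if (q <= 0) stop("cannot set exposure: image is empty", call. = FALSE)
  0.95 / q
}

normalize_scenes <- function(x) {
  if (inherits(x, "hyperspectral_scene")) return(list(x))
  if (is.list(x) && all(vapply(x, inherits, logical(1),
                               "hyperspectral_scene"))) return(x)
  stop("expected a hyperspectral scene or list of scenes", call. = FALSE)
}

#' Synthesize an RGB image through a filter and camera response
#'
#' @param scene A scene from [make_scene()] (or any list with `cube` and
#'   `wavelengths`).
#' @param filter_curve A [spectral_curve()] of filter transmittance, or
#'   `NULL` for the no-filter baseline (all ones).
#' @param csr Camera response; defaults to [default_csr()] on the scene
#'   grid.
#' @param exposure Scalar exposure, or `"auto"` to derive it from this
#'   scene's no-filter image.
#' @param clip Clip to `[0, 1]` after exposure (default TRUE).
#' @return H x W x 3 numeric array of class `rgb_image`.
#' @export
synthesize_rgb <- function(scene, filter_curve = NULL, csr = NULL,
                           exposure = "auto", clip = TRUE) {
  wl <- scene$wavelengths
  cs <- if (is.null(csr)) default_csr(wl) else resample_csr(csr, wl)
  fv <- if (is.null(filter_curve)) rep(1, length(wl)) else {
    resample_curve(filter_curve, wl)$value
  }
  if (identical(exposure, "auto")) {
    exposure <- auto_exposure(scene, cs)
  }
  raw <- integrate_channels(scene$cube, wl, fv, cs) * exposure
  if (clip) {
    raw[raw < 0] <- 0
    raw[raw > 1] <- 1
  }
  structure(raw, class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  cat(sprintf("<rgb_image> %d x %d, range [%.3f, %.3f]\n",
              dim(x)[1], dim(x)[2], min(x), max(x)))
  invisible(x)
}
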