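#' Wavelength grids and spectral curves
#'
#' A spectral grid is a strictly increasing vector of vacuum wavelengths in
#' nanometres. A spectral curve is a tibble with columns `wavelength` (nm)
#' and `value` (dimensionless transmittance, reflectance or response),
#' carrying class `"spectral_curve"` so it can be plotted and resampled.
#'
#' @name spectral-grid
NULL

#' Construct a wavelength grid
#'
#' @param from,to Range of vacuum wavelengths, nm.
#' @param by Step, nm.
#' @return Numeric vector of strictly increasing wavelengths.
#' @examples
#' g <- spectral_grid(400, 800, 2)
#' length(g) # 201
#' @export
spectral_grid <- function(from = 400, to = 800, by = 2) {
  g <- seq(from, to, by = by)
  validate_grid(g)
  g
}

#' Default design grid: 400-800 nm in 2 nm steps (N = 201)
#' @return Numeric wavelength vector.
#' @export
default_grid <- function() spectral_grid(400, 800, 2)

validate_grid <- function(wavelengths) {
  if (length(wavelengths) < 1L || !is.numeric(wavelengths)) {
    stop("grid must contain at least one wavelength", call. = FALSE)
  }
  if (any(!is.finite(wavelengths)) || any(wavelengths <= 0)) {
    stop("wavelengths must be finite and > 0", call. = FALSE)
  }
  if (length(wavelengths) > 1L && any(diff(wavelengths) <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  invisible(wavelengths)
}

#' Build a spectral curve
#'
#' @param wavelength Wavelengths, nm, strictly increasing.
#' @param value Curve values (transmittance/response), same length.
#' @return A tibble of class `spectral_curve`.
#' @export
spectral_curve <- function(wavelength, value) {
  validate_grid(wavelength)
  if (length(value) != length(wavelength)) {
    stop("wavelength and value must have equal length", call. = FALSE)
  }
  if (any(!is.finite(value))) stop("curve values must be finite", call. = FALSE)
  out <- tibble::tibble(wavelength = as.numeric(wavelength),
                        value = as.numeric(value))
  class(out) <- c("spectral_curve", class(out))
  out
}

#' Resample a spectral curve onto a new grid
#'
#' Linear interpolation; outside the curve's domain the edge value is held.
#' Interpolated values are clipped to the range of the original curve.
#'
#' @param curve A [spectral_curve()].
#' @param grid Target wavelength vector.
#' @return A `spectral_curve` on `grid`.
#' @export
resample_curve <- function(curve, grid) {
  if (nrow(curve) == 0L) stop("cannot resample an empty curve", call. = FALSE)
  validate_grid(grid)
  v <- stats::approx(curve$wavelength, curve$value, xout = grid,
                     method = "linear", rule = 2)$y
  v <- pmin(pmax(v, min(curve$value)), max(curve$value))
  spectral_curve(grid, v)
}

#' All-ones transmittance curve (the no-filter baseline)
#'
#' @param grid Wavelength vector.
#' @return A `spectral_curve` equal to 1 everywhere.
#' @export
no_filter_curve <- function(grid = default_grid()) {
  spectral_curve(grid, rep(1, length(grid)))
}

#' Mean absolute error between two spectral curves
#'
#' @param curve_a,curve_b Curves on the same wavelength grid (tibbles with
#'   `wavelength` and `value`, or bare numeric vectors of equal length).
#' @return Scalar MAE.
#' @export
mae_curve <- function(curve_a, curve_b) {
  a <- curve_values(curve_a)
  b <- curve_values(curve_b)
  if (is.data.frame(curve_a) && is.data.frame(curve_b)) {
    if (nrow(curve_a) != nrow(curve_b) ||
        max(abs(curve_a$wavelength - curve_b$wavelength)) > 1e-9) {
      stop("curves are not on the same wavelength grid", call. = FALSE)
    }
  } else if (length(a) != length(b)) {
    stop("curves are not on the same wavelength grid", call. = FALSE)
  }
  mean(abs(a - b))
}

curve_values <- function(x) {
  if (is.data.frame(x)) x$value else as.numeric(x)
}

#' @export
print.spectral_curve <- function(x, ...) {
  cat(sprintf("<spectral_curve> %d points, %g-%g nm, values [%.3g, %.3g]\n",
              nrow(x), min(x$wavelength), max(x$wavelength),
              min(x$value), max(x$value)))
  NextMethod()
}

#' @importFrom ggplot2 autoplot
#' @export
autoplot.spectral_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$wavelength, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)", y = "value") +
    ggplot2::ylim(0, NA)
}
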