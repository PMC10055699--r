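#' Synthetic inputs: target curves, known-truth stacks, pepper/leaf scenes
#'
#' The design targets and the greenhouse imagery the pipeline was built
#' around are not publicly available, so every input can be generated
#' here: smooth band-pass-like target transmittance curves, seeded random
#' stacks with known spectra (ground truth for recovery experiments), and
#' two-class hyperspectral scenes of ellipse-shaped "peppers" on a
#' leaf-textured background whose reflectance spectra are deliberately
#' near-color (correlation > 0.9) yet spectrally separable.
#'
#' @name synthetic
NULL

#' Smooth band-pass-like target transmittance curve
#'
#' Built from a product of two logistic edges; `notch` is the pointwise
#' complement of `bandpass`, and `double_band` sums two displaced
#' pass-bands.
#'
#' @param kind `"bandpass"`, `"notch"` or `"double_band"`.
#' @param center Pass-band center, nm.
#' @param width Full width between the logistic midpoints, nm.
#' @param edge_steepness Logistic scale of the edges, nm (smaller =
#'   steeper).
#' @param grid Wavelength vector, nm.
#' @param separation Center-to-center distance of the two bands for
#'   `double_band`, nm.
#' @return A [spectral_curve()] (class `target_curve` prepended), values
#'   in `[0, 1]`.
#' @examples
#' tc <- make_target_curve("bandpass", center = 550, width = 60)
#' @export
make_target_curve <- function(kind = c("bandpass", "notch", "double_band"),
                              center = 550, width = 60, edge_steepness = 5,
                              grid = default_grid(), separation = 120) {
  kind <- match.arg(kind)
  band <- function(c0, w) {
    stats::plogis((grid - (c0 - w / 2)) / edge_steepness) *
      stats::plogis(((c0 + w / 2) - grid) / edge_steepness)
  }
  v <- switch(kind,
    bandpass = band(center, width),
    notch = 1 - band(center, width),
    double_band = pmin(band(center - separation / 2, width) +
                         band(center + separation / 2, width), 1)
  )
  out <- spectral_curve(grid, pmin(pmax(v, 0), 1))
  class(out) <- c("target_curve", class(out))
  out
}

#' Seeded random stack with known spectra (recovery ground truth)
#'
#' Random thicknesses in `[30, 250]` nm on the alternating 2.3/1.46
#' structure on glass, plus its unpolarized transmittance at normal and
#' oblique incidence computed by the transfer matrix method.
#'
#' @param num_layers Number of inner layers (>= 1).
#' @param seed Integer seed; same seed reproduces stack and spectra.
#' @param theta1 Oblique angle, radians.
#' @param grid Wavelength vector, nm.
#' @return List: `stack`, `spectrum_0` / `spectrum_1`
#'   (full `spectral_response` at each angle), `T0` / `T1`
#'   (unpolarized curves), `seed`.
#' @export
make_known_stack <- function(num_layers = 10, seed = 1L,
                             theta1 = 20 * pi / 180, grid = default_grid()) {
  stopifnot(num_layers >= 1)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  d <- stats::runif(num_layers, 30, 250)
  stack <- alternating_stack(d)
  list(stack = stack,
       spectrum_0 = transmittance_spectrum(stack, 0, grid),
       spectrum_1 = transmittance_spectrum(stack, theta1, grid),
       T0 = unpolarized_T(stack, 0, grid),
       T1 = unpolarized_T(stack, theta1, grid),
       seed = as.integer(seed))
}

#' Reflectance spectra of the synthetic material classes
#'
#' Pepper and leaf are both green-peaked with a red-edge rise — the
#' near-color premise: their spectra correlate above 0.9 on the default
#' grid so their RGB appearance overlaps, yet the pepper peak is narrower,
#' slightly blue-shifted and its red edge steeper, so a per-pixel spectral
#' classifier separates them easily. Background is broadband low
#' reflectance.
#'
#' @param grid Wavelength vector, nm.
#' @return Named list of [spectral_curve()]s: `pepper`, `leaf`,
#'   `background`.
#' @export
material_spectra <- function(grid = default_grid()) {
  leaf <- 0.05 + 0.30 * exp(-((grid - 552) / 42)^2) +
    0.45 * stats::plogis((grid - 710) / 12)
  pepper <- 0.04 + 0.42 * exp(-((grid - 535) / 26)^2) +
    0.50 * stats::plogis((grid - 700) / 9)
  background <- 0.06 + 0.08 * (grid - min(grid)) / max(diff(range(grid)), 1)
  list(pepper = spectral_curve(grid, pmin(pepper, 1)),
       leaf = spectral_curve(grid, pmin(leaf, 1)),
       background = spectral_curve(grid, pmin(background, 1)))
}

#' Scene specification for the synthetic greenhouse generator
#'
#' @param height,width Scene size in pixels.
#' @param n_peppers Number of elliptical pepper blobs.
#' @param axis_range Semi-axis range in pixels, `c(min, max)`.
#' @param illumination A [spectral_curve()] or `NULL` for flat (1).
#' @param noise_sd Additive Gaussian band noise, in units of peak
#'   radiance.
#' @param jitter Per-object multiplicative reflectance jitter scale.
#' @param grid Band wavelengths, nm (default 400-800 nm in 10 nm steps,
#'   41 bands).
#' @param seed Integer seed.
#' @return List of class `scene_spec`.
#' @export
scene_spec <- function(height = 64, width = 64, n_peppers = 3,
                       axis_range = c(6, 14), illumination = NULL,
                       noise_sd = 0.01, jitter = 0.05,
                       grid = spectral_grid(400, 800, 10), seed = 1L) {
  stopifnot(height > 0, width > 0, n_peppers >= 0,
            axis_range[1] > 0, axis_range[2] >= axis_range[1])
  validate_grid(grid)
  structure(list(height = height, width = width, n_peppers = n_peppers,
                 axis_range = axis_range, illumination = illumination,
                 noise_sd = noise_sd, jitter = jitter, grid = grid,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

#' Generate one synthetic two-class hyperspectral scene
#'
#' Ellipse-shaped pepper regions over a leaf-textured background:
#' `cube(x, y, l) = illumination(l) * reflectance_class(x, y)(l) *
#' (1 + jitter) * texture(x, y) + noise`. Fully determined by
#' `spec$seed`.
#'
#' @param spec A [scene_spec()].
#' @param materials Named list from [material_spectra()] (resampled onto
#'   `spec$grid` automatically).
#' @return List of class `hyperspectral_scene`: `cube` (H x W x bands
#'   array), `mask` (H x W integer matrix, 0 = background/leaf,
#'   1 = pepper), `wavelengths`, `spec`.
#' @export
make_scene <- function(spec, materials = material_spectra(spec$grid)) {
  H <- spec$height; W <- spec$width
  grid <- spec$grid; B <- length(grid)
  refl <- lapply(materials, function(m) resample_curve(m, grid)$value)
  illum <- if (is.null(spec$illumination)) rep(1, B) else {
    resample_curve(spec$illumination, grid)$value
  }
  amax <- spec$axis_range[2]
  if (spec$n_peppers > 0 &&
      (2 * amax + 2 > H || 2 * amax + 2 > W)) {
    stop("peppers cannot fit in a scene this small", call. = FALSE)
  }

  old <- local_seed(spec$seed)
  on.exit(restore_seed(old))

  mask <- matrix(0L, H, W)
  jit <- matrix(0, H, W)   # per-object multiplicative jitter field
  xs <- matrix(rep(seq_len(W), each = H), H, W)
  ys <- matrix(rep(seq_len(H), W), H, W)
  for (k in seq_len(spec$n_peppers)) {
    a <- stats::runif(1, spec$axis_range[1], spec$axis_range[2])
    b <- stats::runif(1, spec$axis_range[1], spec$axis_range[2])
    cx <- stats::runif(1, a + 1, W - a - 1)
    cy <- stats::runif(1, b + 1, H - b - 1)
    phi <- stats::runif(1, 0, pi)
    dx <- xs - cx; dy <- ys - cy
    u <- dx * cos(phi) + dy * sin(phi)
    v <- -dx * sin(phi) + dy * cos(phi)
    inside <- (u / a)^2 + (v / b)^2 <= 1
    mask[inside] <- 1L
    jit[inside] <- stats::rnorm(1, 0, spec$jitter)
  }
  # smooth multiplicative leaf texture on the background
  fx <- stats::runif(2, 0.5, 2); fy <- stats::runif(2, 0.5, 2)
  ph <- stats::runif(2, 0, 2 * pi)
  texture <- 1 +
    0.05 * sin(2 * pi * fx[1] * xs / W + ph[1]) *
    sin(2 * pi * fy[1] * ys / H + ph[2]) +
    0.05 * sin(2 * pi * fx[2] * (xs + ys) / (W + H))
  jit[mask == 0L] <- stats::rnorm(1, 0, spec$jitter)   # whole-canopy jitter

  cube <- array(0, dim = c(H, W, B))
  peak <- 0
  pepper_pix <- mask == 1L
  for (b in seq_len(B)) {
    plane <- ifelse(pepper_pix, refl$pepper[b], refl$leaf[b])
    plane <- illum[b] * plane * (1 + jit)
    plane[!pepper_pix] <- plane[!pepper_pix] * texture[!pepper_pix]
    cube[, , b] <- plane
    peak <- max(peak, max(plane))
  }
  if (spec$noise_sd > 0) {
    cube <- cube + array(stats::rnorm(H * W * B, 0, spec$noise_sd * peak),
                         dim = dim(cube))
  }
  cube[cube < 0] <- 0
  structure(list(cube = cube, mask = mask, wavelengths = grid, spec = spec),
            class = "hyperspectral_scene")
}

#' @export
print.hyperspectral_scene <- function(x, ...) {
  cat(sprintf("<hyperspectral_scene> %d x %d x %d bands (%g-%g nm), %d pepper px\n",
              dim(x$cube)[1], dim(x$cube)[2], dim(x$cube)[3],
              min(x$wavelengths), max(x$wavelengths), sum(x$mask)))
  invisible(x)
}

#' Nearest-class-spectrum pixel classifier (oracle)
#'
#' Assigns each pixel to pepper or leaf by correlation with the class
#' reflectance spectra; used to certify that synthetic scenes are
#' solvable from spectra even though the classes are near-color in RGB.
#'
#' @param scene A scene from [make_scene()].
#' @param materials Class spectra on the scene's grid.
#' @return H x W integer matrix of predicted labels (1 = pepper).
#' @export
classify_pixels_spectral <- function(scene,
                                     materials =
                                       material_spectra(scene$wavelengths)) {
  B <- dim(scene$cube)[3]
  X <- matrix(scene$cube, ncol = B)        # pixels x bands
  Xc <- X - rowMeans(X)
  score <- function(ref) {
    r <- resample_curve(ref, scene$wavelengths)$value
    rc <- r - mean(r)
    as.numeric(Xc %*% rc) / (sqrt(rowSums(Xc^2)) * sqrt(sum(rc^2)) + 1e-12)
  }
  sp <- score(materials$pepper)
  sl <- score(materials$leaf)
  matrix(as.integer(sp > sl), dim(scene$cube)[1], dim(scene$cube)[2])
}

#' Generate a seeded multi-scene dataset with disjoint splits
#'
#' @param n_scenes Total number of scenes.
#' @param spec A [scene_spec()] template (its `seed` is ignored; per-scene
#'   seeds derive from `seed`).
#' @param split Fractions `c(train, val, test)`, summing to 1.
#' @param seed Master seed.
#' @return List of class `scene_dataset` with `train`, `val`, `test`
#'   scene lists and a `manifest` tibble of per-scene seeds and splits.
#' @export
make_dataset <- function(n_scenes, spec = scene_spec(),
                         split = c(0.6, 0.2, 0.2), seed = 1L) {
  if (abs(sum(split) - 1) > 1e-9) {
    stop("split fractions must sum to 1", call. = FALSE)
  }
  n_train <- round(n_scenes * split[1])
  n_val <- round(n_scenes * split[2])
  n_test <- n_scenes - n_train - n_val
  scene_seeds <- seed * 10000L + seq_len(n_scenes)   # distinct by construction
  roles <- rep(c("train", "val", "test"), c(n_train, n_val, n_test))
  scenes <- lapply(scene_seeds, function(s) {
    sp <- spec; sp$seed <- as.integer(s)
    make_scene(sp)
  })
  manifest <- tibble::tibble(scene = seq_len(n_scenes), seed = scene_seeds,
                             role = roles)
  structure(list(train = scenes[roles == "train"],
                 val = scenes[roles == "val"],
                 test = scenes[roles == "test"],
                 manifest = manifest, master_seed = as.integer(seed)),
            class = "scene_dataset")
}
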