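# Hyperspectral-to-RGB synthesis: resampling, linearity, exposure,
# diagonal-weight commutation, and the color-shift regression.

test_that("curve resampling is exact for on-grid, constant and linear input", {
  g <- spectral_grid(400, 700, 50)
  cv <- spectral_curve(g, c(0.1, 0.3, 0.5, 0.6, 0.4, 0.2, 0.1))
  expect_equal(resample_curve(cv, g)$value, cv$value, tolerance = 1e-15)

  const <- spectral_curve(c(400, 800), c(0.7, 0.7))
  expect_equal(resample_curve(const, spectral_grid(450, 750, 10))$value,
               rep(0.7, 31))

  ramp <- spectral_curve(seq(400, 800, 100), seq(0, 1, length.out = 5))
  mid <- resample_curve(ramp, seq(450, 750, 100))
  expect_equal(mid$value, c(0.125, 0.375, 0.625, 0.875), tolerance = 1e-12)

  expect_error(resample_curve(spectral_curve(500, 0.5)[0, ], g), "empty")
})

test_that("the no-filter curve reproduces unfiltered integration exactly", {
  sc <- make_scene(scene_spec(height = 16, width = 16, n_peppers = 2,
                              axis_range = c(2, 4), seed = 5))
  expo <- auto_exposure(sc)
  img_none <- synthesize_rgb(sc, NULL, exposure = expo)
  img_ones <- synthesize_rgb(sc, no_filter_curve(sc$wavelengths),
                             exposure = expo)
  expect_equal(img_ones, img_none, tolerance = 1e-15)
  expect_equal(mae_curve(no_filter_curve(sc$wavelengths),
                         no_filter_curve(sc$wavelengths)), 0)
})

test_that("synthesis is linear in the filter and monotone in transmittance", {
  sc <- make_scene(scene_spec(height = 16, width = 16, n_peppers = 2,
                              axis_range = c(2, 4), seed = 6))
  g <- sc$wavelengths
  filt <- make_target_curve("bandpass", 550, 120, grid = g)
  expo <- 1   # fixed, unclipped regime
  a <- synthesize_rgb(sc, filt, exposure = expo, clip = FALSE)
  half <- spectral_curve(g, filt$value * 0.5)
  b <- synthesize_rgb(sc, half, exposure = expo, clip = FALSE)
  expect_equal(unclass(b), unclass(a) * 0.5, tolerance = 1e-12)

  # pointwise larger transmittance never decreases any unclipped value
  larger <- spectral_curve(g, pmin(filt$value + 0.2, 1))
  cc <- synthesize_rgb(sc, larger, exposure = expo, clip = FALSE)
  expect_true(all(cc >= a - 1e-15))
})

test_that("a delta camera response collapses the integral to one band", {
  sc <- make_scene(scene_spec(height = 8, width = 8, n_peppers = 1,
                              axis_range = c(1, 2), noise_sd = 0, seed = 7))
  g <- sc$wavelengths
  b0 <- 21   # an interior band
  resp <- rep(0, length(g)); resp[b0] <- 1
  csr <- tibble::tibble(wavelength = g, R = resp, G = resp, B = resp)
  filt <- make_target_curve("bandpass", 560, 100, grid = g)
  img <- synthesize_rgb(sc, filt, csr, exposure = 1, clip = FALSE)
  w <- diff(g)[1]   # uniform grid: interior trapezoid weight
  expect_equal(img[, , 1], sc$cube[, , b0] * filt$value[b0] * w,
               tolerance = 1e-12)
})

test_that("filter and camera response commute as diagonal weights", {
  sc <- make_scene(scene_spec(height = 8, width = 8, n_peppers = 1,
                              axis_range = c(1, 2), seed = 8))
  g <- sc$wavelengths
  filt <- make_target_curve("bandpass", 550, 80, grid = g)
  csr <- default_csr(g)
  # fold the filter into the CSR instead of applying it separately
  csr_folded <- tibble::tibble(wavelength = g, R = csr$R * filt$value,
                               G = csr$G * filt$value, B = csr$B * filt$value)
  a <- synthesize_rgb(sc, filt, csr, exposure = 1, clip = FALSE)
  b <- synthesize_rgb(sc, NULL, csr_folded, exposure = 1, clip = FALSE)
  expect_equal(unclass(a), unclass(b), tolerance = 1e-12)
})

test_that("auto exposure maps the 99th percentile to 0.95", {
  sc <- make_scene(scene_spec(height = 16, width = 16, n_peppers = 2,
                              axis_range = c(2, 4), seed = 9))
  expo <- auto_exposure(sc)
  raw <- synthesize_rgb(sc, NULL, exposure = expo, clip = FALSE)
  expect_equal(as.numeric(stats::quantile(raw, 0.99)), 0.95,
               tolerance = 1e-9)
})

test_that("a blue-shifted band-pass changes the G/R balance of leaf pixels", {
  # operationalizes the motivating color shift: the same leaf spectrum
  # seen through the 20-degree curve of a band-pass yields a different
  # green/red ratio than through the 0-degree curve
  sc <- make_scene(scene_spec(height = 8, width = 8, n_peppers = 0,
                              noise_sd = 0, jitter = 0, seed = 10))
  st <- bandpass_stack(m = 3)
  c0 <- unpolarized_T(st, 0, sc$wavelengths)
  c20 <- unpolarized_T(st, deg(20), sc$wavelengths)
  i0 <- synthesize_rgb(sc, c0, exposure = 1, clip = FALSE)
  i20 <- synthesize_rgb(sc, c20, exposure = 1, clip = FALSE)
  gr0 <- i0[1, 1, 2] / i0[1, 1, 1]
  gr20 <- i20[1, 1, 2] / i20[1, 1, 1]
  expect_gt(abs(gr20 - gr0) / gr0, 0.02)
})
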