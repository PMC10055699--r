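# Transfer-matrix core: Snell angles, Fresnel interfaces, matrices,
# power coefficients, spectra and their thickness gradients.

test_that("refraction angles obey Snell's law and its invariance", {
  st <- layer_stack(index = c(2.3, 1.46, 1.52), thickness = c(50, 80, 10))

  expect_equal(refraction_angles(st, 0), rep(0, 5))

  ang <- refraction_angles(st, deg(20))
  n_all <- c(1, 2.3, 1.46, 1.52, 1.52)
  expect_equal(n_all * sin(ang), rep(sin(deg(20)), 5), tolerance = 1e-12)
  # substrate angle equals the closed-form arcsine, with or without layers
  expect_equal(ang[5], asin(sin(deg(20)) / 1.52), tolerance = 1e-12)
  bare <- layer_stack()
  expect_equal(refraction_angles(bare, deg(20))[2], ang[5])

  # total internal reflection from a dense injection medium is detected
  dense <- layer_stack(index = 1.1, thickness = 100, n0 = 1.9)
  expect_error(refraction_angles(dense, deg(80)), "total internal reflection")
  expect_error(refraction_angles(st, -0.1), "theta0")
})

test_that("Fresnel interface coefficients match direct arithmetic", {
  # no interface
  for (pol in c("s", "p")) {
    fr <- fresnel_interface(1.5, 1.5, 0.3, 0.3, pol)
    expect_equal(fr$r, 0)
    expect_equal(fr$t, 1)
  }
  # normal incidence air -> glass 1.5
  fr <- fresnel_interface(1, 1.5, 0, 0, "s")
  expect_equal(fr$r, -0.2)
  expect_equal(abs(fr$r)^2, 0.04)
  # Brewster: r_p vanishes to machine precision
  thB <- atan(1.52 / 1)
  th2 <- asin(sin(thB) / 1.52)
  expect_lt(abs(fresnel_interface(1, 1.52, thB, th2, "p")$r), 1e-12)
})

test_that("single-layer matrices follow the phase/interface factorization", {
  expect_equal(layer_matrix(0, 0, 1), diag(2) + 0i)
  M <- layer_matrix(pi / 2, 0, 1)
  expect_equal(M, matrix(c(-1i, 0, 0, 1i), 2, 2), tolerance = 1e-15)
  expect_error(layer_matrix(0.3, 0.2, 0), "t = 0")

  # det(M) for an s-pol interface equals n2 cos(th2) / (n1 cos(th1)):
  # det of (1/t^2) [[1, r], [r, 1]] = (1 - r^2)/t^2 = t't/t^2 = t'/t
  n1 <- 1.2; n2 <- 2.1; th1 <- deg(25); th2 <- asin(n1 * sin(th1) / n2)
  fr <- fresnel_interface(n1, n2, th1, th2, "s")
  M <- layer_matrix(0.7, fr$r, fr$t)
  detM <- M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]
  expect_equal(Re(detM), n2 * cos(th2) / (n1 * cos(th1)), tolerance = 1e-12)
  expect_lt(abs(Im(detM)), 1e-12)
})

test_that("stack matrix and coefficients reduce to bare-interface Fresnel", {
  trivial <- layer_stack(n0 = 1.52, n_sub = 1.52)
  expect_equal(stack_matrix(trivial, 0, 550, "s"), diag(2) + 0i)
  expect_equal(stack_coefficients(diag(2) + 0i), list(r = 0 + 0i, t = 1 + 0i))

  bare <- layer_stack()   # air | glass
  for (pol in c("s", "p")) {
    M <- stack_matrix(bare, deg(15), 550, pol)
    co <- stack_coefficients(M)
    th2 <- asin(sin(deg(15)) / 1.52)
    fr <- fresnel_interface(1, 1.52, deg(15), th2, pol)
    expect_equal(co$r, fr$r + 0i, tolerance = 1e-12)
    expect_equal(co$t, fr$t + 0i, tolerance = 1e-12)
  }
  # normal-incidence air|glass amplitude reflection is -0.2 scaled:
  co <- stack_coefficients(stack_matrix(bare, 0, 550, "s"))
  expect_equal(Re(co$r), (1 - 1.52) / (1 + 1.52), tolerance = 1e-12)

  # a zero-thickness layer matching its neighbour changes nothing
  padded <- layer_stack(index = c(2.0, 2.0, 1.4), thickness = c(100, 0, 80))
  plain <- layer_stack(index = c(2.0, 1.4), thickness = c(100, 80))
  expect_equal(stack_matrix(padded, deg(10), 600, "p"),
               stack_matrix(plain, deg(10), 600, "p"), tolerance = 1e-12)
})

test_that("air|glass power transmittance matches the closed form", {
  bare <- layer_stack()
  sp <- transmittance_spectrum(bare, 0, spectral_grid(500, 600, 50))
  expect_equal(sp$T_s, rep(4 * 1.52 / 2.52^2, 3), tolerance = 1e-12)
  expect_equal(sp$T_p, sp$T_s, tolerance = 1e-15)
})

test_that("a symmetric lossless etalon transmits fully at resonance", {
  # half-wave layer (absent-layer condition): T equals the bare interface
  # at the design wavelength; a symmetric same-media etalon hits T = 1
  etalon <- layer_stack(index = 2.0, thickness = 550 / (2 * 2.0),
                        n0 = 1.52, n_sub = 1.52)
  sp <- transmittance_spectrum(etalon, 0, 550)
  expect_equal(sp$T_s, 1, tolerance = 1e-12)
})

test_that("energy is conserved and polarizations degenerate at normal incidence", {
  grid <- default_grid()
  for (seed in 1:5) {
    st <- random_stack(n = c(4, 10, 20, 40, 60)[seed], seed = seed)
    for (th in deg(c(0, 20, 40))) {
      sp <- transmittance_spectrum(st, th, grid)
      expect_lt(max(abs(sp$T_s + sp$R_s - 1)), 1e-9)
      expect_lt(max(abs(sp$T_p + sp$R_p - 1)), 1e-9)
      expect_true(all(sp$T_s >= 0 & sp$T_s <= 1 + 1e-12))
      expect_true(all(sp$T_p >= 0 & sp$T_p <= 1 + 1e-12))
    }
    sp0 <- transmittance_spectrum(st, 0, grid)
    expect_lt(max(abs(sp0$T_s - sp0$T_p)), 1e-12)
  }
})

test_that("quarter-wave reflector matches the admittance closed form", {
  for (m in c(3, 5)) {
    st <- alternating_stack(qw_thickness(2 * m))
    sp <- transmittance_spectrum(st, 0, 550)
    expect_equal(sp$R_s, quarter_wave_R_oracle(2.3, 1.46, m),
                 tolerance = 1e-8)
  }
})

test_that("a band-pass stack blue-shifts at oblique incidence", {
  st <- bandpass_stack(m = 3)
  grid <- spectral_grid(480, 620, 0.5)
  p0 <- peak_wavelength(st, 0, grid)
  p20 <- peak_wavelength(st, deg(20), grid)
  expect_equal(p0, 550, tolerance = 1)
  expect_lt(p20, p0)
})

test_that("analytic thickness gradients match central finite differences", {
  st <- random_stack(n = 10, seed = 7)
  grid <- spectral_grid(420, 780, 20)
  h <- 1e-3
  for (pol in c("s", "p")) {
    gr <- transmittance_gradient(st, deg(20), grid, pol)
    for (l in seq_len(10)) {
      up <- st$thickness; up[l] <- up[l] + h
      dn <- st$thickness; dn[l] <- dn[l] - h
      fd <- (transmittance_spectrum(set_thickness(st, up), deg(20), grid) -
               transmittance_spectrum(set_thickness(st, dn), deg(20), grid))
      fd <- if (pol == "s") fd$T_s else fd$T_p
      fd <- fd / (2 * h)
      expect_lt(max(abs(gr$dT[, l] - fd) / pmax(abs(fd), 1e-6)), 1e-5)
    }
  }
})

test_that("degenerate stacks raise explicit errors", {
  expect_error(layer_stack(index = 0.9, thickness = 10), "indices")
  expect_error(layer_stack(index = 1.5, thickness = -5), "thickness")
  expect_error(spectral_grid(800, 400, 10))
})
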