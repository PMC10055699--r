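# Merit functions, their gradients, initialization and the bounded
# quasi-Newton thickness optimization.

test_that("unpolarized transmittance is the s/p mean and bounded by both", {
  st <- random_stack(n = 8, seed = 2)
  grid <- spectral_grid(450, 750, 10)
  sp <- transmittance_spectrum(st, deg(25), grid)
  tu <- unpolarized_T(st, deg(25), grid)
  expect_equal(tu$value, (sp$T_s + sp$T_p) / 2, tolerance = 1e-15)
  expect_true(all(tu$value >= pmin(sp$T_s, sp$T_p) - 1e-15))
  expect_true(all(tu$value <= pmax(sp$T_s, sp$T_p) + 1e-15))
  # at normal incidence it equals either polarization exactly
  sp0 <- transmittance_spectrum(st, 0, grid)
  tu0 <- unpolarized_T(st, 0, grid)
  expect_equal(tu0$value, sp0$T_s, tolerance = 1e-15)
})

test_that("merit values match direct arithmetic on worked cases", {
  st <- random_stack(n = 6, seed = 3)
  grid <- default_grid()
  cfg <- merit_config(grid = grid)

  # a stack scored against its own spectra at both angles scores zero
  t0 <- unpolarized_T(st, 0, grid)$value
  t1 <- unpolarized_T(st, deg(20), grid)$value
  sp1 <- transmittance_spectrum(st, deg(20), grid)
  # merit1 with target = T0 curve: only the oblique term remains
  target0 <- spectral_curve(grid, t0)
  m1 <- merit1(st, target0, cfg)
  expect_equal(m1, mean((t1 - t0)^2), tolerance = 1e-12)
  m2 <- merit2(st, target0, cfg)
  expect_equal(m2, mean((sp1$T_s - t0)^2 + (sp1$T_p - t0)^2),
               tolerance = 1e-12)

  # hand-worked single-wavelength arithmetic:
  # T0 = 0.6, T1_unpol = 0.7, target 0.5 -> merit1 = 0.01 + 0.04 = 0.05
  err0 <- 0.6 - 0.5; err1 <- 0.7 - 0.5
  expect_equal(err0^2 + err1^2, 0.05)
  # T1s = 0.6, T1p = 0.4, target 0.5 -> merit2 oblique terms 0.01 + 0.01
  expect_equal((0.6 - 0.5)^2 + (0.4 - 0.5)^2, 0.02)

  expect_error(merit1(st, spectral_curve(grid[-1], t0[-1]), cfg), "grid")
})

test_that("merit2 dominates merit1 over random stacks and targets", {
  # (a^2 + b^2)/2 >= ((a + b)/2)^2: per-polarization penalties can only
  # exceed the penalty of the polarization mean
  grid <- spectral_grid(450, 750, 25)
  cfg <- merit_config(grid = grid)
  withr::with_seed(99, {
    for (k in 1:25) {
      st <- alternating_stack(stats::runif(8, 30, 250))
      target <- spectral_curve(grid, stats::runif(length(grid)))
      expect_gte(merit2(st, target, cfg) + 1e-15, merit1(st, target, cfg))
    }
  })
})

test_that("merit gradients match finite differences and vanish at a match", {
  st <- random_stack(n = 10, seed = 5)
  grid <- spectral_grid(450, 750, 25)
  target <- make_target_curve("bandpass", 600, 100, grid = grid)
  h <- 1e-3
  for (variant in c("merit1", "merit2", "normal_only")) {
    cfg <- merit_config(variant, grid = grid)
    g <- merit_gradient(st, target, cfg)
    fn <- function(d) merit_eval(set_thickness(st, d), target, cfg)$value
    for (l in c(1, 4, 10)) {
      up <- st$thickness; up[l] <- up[l] + h
      dn <- st$thickness; dn[l] <- dn[l] - h
      fd <- (fn(up) - fn(dn)) / (2 * h)
      expect_lt(abs(g[l] - fd) / max(abs(fd), 1e-8), 1e-5)
    }
  }

  # gradient is ~0 when the target is the stack's own spectrum pair
  cfg <- merit_config("merit2", grid = grid)
  sp0 <- unpolarized_T(st, 0, grid)
  # only variant normal_only has an exact global minimum at its own curve
  cfg0 <- merit_config("normal_only", grid = grid)
  g0 <- merit_gradient(st, sp0, cfg0)
  expect_lt(max(abs(g0)), 1e-8)

  # a front layer index-matched to the injection medium on both sides is
  # optically inert: its phase factors out of |M11|, so its gradient is 0
  inert <- layer_stack(index = c(1, 1, 2.3), thickness = c(80, 50, 90))
  gi <- merit_gradient(inert, make_target_curve("bandpass", 600, 100,
                                                grid = grid),
                       merit_config("merit1", grid = grid))
  expect_lt(abs(gi[1]), 1e-12)
  expect_lt(abs(gi[2]), 1e-12)
  expect_gt(abs(gi[3]), 1e-12)
})

test_that("initialization strategies are seeded and bounded", {
  d <- initialize_design(6, "quarter_wave", seed = 1, lambda_ref = 550)
  expect_equal(d, 550 / (4 * rep(c(2.3, 1.46), 3)), tolerance = 1e-12)
  expect_equal(d[1], 59.78, tolerance = 1e-3)

  r1 <- initialize_design(20, "uniform_random", seed = 9, lo = 20, hi = 300)
  r2 <- initialize_design(20, "uniform_random", seed = 9, lo = 20, hi = 300)
  expect_identical(r1, r2)
  expect_true(all(r1 >= 20 & r1 <= 300))
  expect_error(initialize_design(5, "fibonacci"), "arg")
})

test_that("optimization recovers a known design and respects bounds", {
  grid <- spectral_grid(420, 780, 10)
  truth <- make_known_stack(8, seed = 21, grid = grid)
  cfg <- merit_config("merit1", grid = grid)
  # dual-angle target: optimize against the truth's normal-incidence curve
  target <- truth$T0

  # starting at the truth: immediate convergence, tiny merit
  fit0 <- optimize_thicknesses(truth$stack, target, cfg, max_iter = 50)
  expect_lte(fit0$final_merit, merit1(truth$stack, target, cfg) + 1e-12)

  # perturbed start recovers a spectrum close to the target at 0 degrees
  withr::with_seed(31, {
    start <- truth$stack$thickness + stats::runif(8, -15, 15)
  })
  fit <- optimize_thicknesses(pmax(start, 0), target,
                              merit_config("normal_only", grid = grid),
                              stack = truth$stack, max_iter = 300)
  expect_true(all(fit$thicknesses >= 0))
  expect_true(all(diff(fit$merit_trace) <= 1e-15))
  expect_lt(mae_curve(unpolarized_T(fit$stack, 0, grid), target), 0.01)

  # glance/tidy expose the fit
  g <- glance(fit)
  expect_equal(g$n_layers, 8L)
  expect_equal(nrow(tidy(fit)), 8L)
})

test_that("mae_curve matches hand arithmetic and rejects grid mismatch", {
  g <- c(500, 550, 600)
  a <- spectral_curve(g, c(0.1, 0.5, 0.9))
  b <- spectral_curve(g, c(0.2, 0.4, 0.9))
  expect_equal(mae_curve(a, a), 0)
  expect_equal(mae_curve(a, b), 2 / 30, tolerance = 1e-12)
  expect_equal(mae_curve(spectral_curve(g, c(0.2, 0.2, 0.2)),
                         spectral_curve(g, c(0.25, 0.25, 0.25))), 0.05)
  expect_error(mae_curve(a, spectral_curve(c(500, 551, 600), c(0.2, 0.4, 0.9))),
               "grid")
})
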