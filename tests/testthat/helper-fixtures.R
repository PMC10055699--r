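# Shared fixtures, built in code.

deg <- function(x) x * pi / 180

# random lossless alternating stack with seeded thicknesses
random_stack <- function(n = 10, seed = 1, lo = 30, hi = 250) {
  withr::with_seed(seed, alternating_stack(stats::runif(n, lo, hi)))
}

# independent closed-form oracle: Fresnel power coefficients of a single
# interface (normal or oblique), computed without the transfer matrix
fresnel_power_oracle <- function(n1, n2, theta1, polarization) {
  theta2 <- asin(n1 * sin(theta1) / n2)
  c1 <- cos(theta1); c2 <- cos(theta2)
  if (polarization == "s") {
    r <- (n1 * c1 - n2 * c2) / (n1 * c1 + n2 * c2)
  } else {
    r <- (n2 * c1 - n1 * c2) / (n2 * c1 + n1 * c2)
  }
  list(R = r^2, T = 1 - r^2)
}

# independent closed-form oracle: quarter-wave (HL)^m reflector at its
# design wavelength, by the admittance transformation Y -> n^2 / Y
quarter_wave_R_oracle <- function(n_high, n_low, m, n0 = 1, n_sub = 1.52) {
  Y <- n_sub
  for (k in seq_len(m)) {
    Y <- n_low^2 / Y     # layer nearest the substrate is L
    Y <- n_high^2 / Y
  }
  ((n0 - Y) / (n0 + Y))^2
}

# quarter-wave thicknesses for an alternating 2.3/1.46 stack
qw_thickness <- function(n_layers, lambda0 = 550, n_high = 2.3, n_low = 1.46) {
  idx <- rep(c(n_high, n_low), length.out = n_layers)
  lambda0 / (4 * idx)
}

# Fabry-Perot band-pass stack: quarter-wave mirror, half-wave low-index
# spacer, mirror (design wavelength lambda0)
bandpass_stack <- function(m = 3, lambda0 = 550, n_high = 2.3, n_low = 1.46) {
  dH <- lambda0 / (4 * n_high); dL <- lambda0 / (4 * n_low)
  mirror_d <- rep(c(dH, dL), m)[seq_len(2 * m - 1)]    # ends on H
  mirror_i <- rep(c(n_high, n_low), m)[seq_len(2 * m - 1)]
  spacer_d <- lambda0 / (2 * n_low)
  layer_stack(index = c(mirror_i, n_low, rev(mirror_i)),
              thickness = c(mirror_d, spacer_d, rev(mirror_d)))
}

# tiny scene set for fast segmentation tests
tiny_dataset <- function(n = 4, seed = 42, size = 32) {
  make_dataset(n, scene_spec(height = size, width = size, n_peppers = 2,
                             axis_range = c(4, 8)),
               split = c(0.5, 0, 0.5), seed = seed)
}
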