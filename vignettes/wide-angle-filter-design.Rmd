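---
title: "Wide-angular-tolerance thin-film filter design: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wide-angular-tolerance thin-film filter design: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(widefilm)
```

## The problem

A dielectric band-pass filter is an interference device: its pass-band is
produced by constructive interference across tens of alternating high/low
refractive-index layers. Interference depends on the optical phase
`2 pi n d cos(theta) / lambda` accumulated in each layer, so when light
arrives obliquely (`theta > 0`), every layer's phase shrinks by `cos(theta)`
and the whole pass-band slides toward shorter wavelengths — the angular
blue shift. For a camera behind such a filter, objects imaged at the edge
of a wide field of view are seen through a different effective filter than
objects on the optical axis, and their apparent colour shifts. That matters
most for *near-colour* discrimination tasks — telling green peppers from
green leaves — where the filter was designed precisely to amplify a small
spectral difference.

`widefilm` addresses this with three connected parts:

1. a transfer-matrix simulator for lossless multilayer stacks with exact
   analytic gradients of transmittance with respect to layer thicknesses;
2. dual-angle merit functions and a bounded quasi-Newton optimizer that
   design a stack to match a target transmittance at normal *and* oblique
   incidence simultaneously;
3. an imaging and evaluation pipeline: hyperspectral scene × filter ×
   camera spectral response → RGB → a small segmentation network, scored
   by mean IoU while transmittance curves are swapped under a frozen
   network.

## The optical model

Light of vacuum wavelength `lambda` enters from the injection medium
(index `n0`, angle `theta0`), crosses inner layers `j = 1..L` (index
`n_j`, thickness `d_j`) and exits into a semi-infinite substrate. Angles
follow Snell's law (`n0 sin theta0 = n_j sin theta_j`); each interface
contributes Fresnel amplitude coefficients `r, t` per polarization, and
each layer a phase `delta_j = d_j k_j` with `k_j = 2 pi n_j cos(theta_j)
/ lambda`. The per-layer factor is

    M_j = diag(e^{-i delta_j}, e^{+i delta_j}) . (1/t_j) [[1, r_j], [r_j, 1]]

and the stack matrix is the ordered product from injection to substrate,
the injection factor carrying zero phase (it contributes only the first
interface). With no light returning from the substrate, the amplitude
coefficients are `r = M[2,1]/M[1,1]`, `t = 1/M[1,1]`, and the power
coefficients `R = |r|^2`, `T = (n_sub cos theta_sub)/(n0 cos theta0)
|t|^2`.

Assumptions and their consequences:

* **Lossless, dispersion-free materials.** Indices are real constants
  (2.3 / 1.46 for the tantala/silica system, 1.52 substrate). Energy
  conservation `R + T = 1` then holds exactly and is enforced in tests to
  1e-9. The complex arithmetic is retained throughout, so absorbing
  indices degrade gracefully, but they are untested and unsupported.
* **Coherent stack, incoherent world.** The calculation stops at entry
  into the substrate; the substrate's back surface is not modelled. A real
  mounted filter adds a ~4% incoherent back-surface reflection that this
  model omits deliberately.
* **Plane waves at a single angle.** A lens integrates over a cone of
  angles; the package evaluates discrete angles (default 0° and 20°),
  which is the granularity at which designs are compared.

### Analytic gradients

Thickness optimization needs `dT/dd_j`. Since only `delta_j` depends on
`d_j`, differentiating the matrix product reduces to a prefix/suffix
decomposition: `dM/dd_j = P_{j-1} . (dM_j/d delta_j) k_j . S_j`, where
prefix rows and suffix columns are accumulated in one forward and one
backward sweep — two extra passes regardless of layer count. Gradients
agree with central finite differences (step 1e-3 nm) to relative error
below 1e-5 on random 10-layer stacks; the finite-difference comparison is
itself part of the test suite, as is the closed-form admittance formula
for quarter-wave reflectors and the direct Fresnel formulas for bare
interfaces.

## Dual-angle merit functions

Given a target curve `T*` on a wavelength grid (default 400–800 nm in
2 nm steps, N = 201 — a visible-range grid; both range and spacing are
configurable), with `T^theta = (T_s + T_p)/2` the unpolarized
transmittance:

* **Merit 1** — `(1/N) sum [ (T^{0} - T*)^2 + (T^{theta1} - T*)^2 ]`:
  the oblique term uses the polarization mean.
* **Merit 2** — `(1/N) sum [ (T^{0} - T*)^2 + (T_p^{theta1} - T*)^2 +
  (T_s^{theta1} - T*)^2 ]`: each oblique polarization is penalized
  separately. Merit 2 ≥ Merit 1 always (quadratic mean ≥ squared mean),
  so it is the stricter objective.
* **normal-only** — the single-angle baseline `(1/N) sum (T^{0} - T*)^2`,
  the design style the dual-angle merits are compared against.

Optimization uses L-BFGS-B (`stats::optim`) with the analytic gradient,
bounds `[0, 1000]` nm per layer (non-negativity is physical; the upper
bound is a practical regularizer), and stopping on merit change below
1e-10, projected-gradient norm below 1e-8, or 500 iterations. The merit
trace records every function evaluation; the reported trace is the
running minimum, i.e. the accepted-iterate envelope. One random restart
(uniform ±15 nm around the start, seeded) is kept as the default
best-of-k guard: the 60-layer normal-only landscape in particular has
poor basins that a single quarter-wave start sometimes falls into.

Initialization is quarter-wave at 550 nm (`d = lambda/(4n)`) with seeded
±10 nm jitter by default; a uniform-random strategy is available. All
randomness flows from integer seeds and every stage is reproducible
bit-for-bit from them.

### The default design task

Sixty alternating 2.3/1.46 layers on glass, air injection, angles 0° and
20°, band-pass target centred at 550 nm, width 80 nm, logistic edges.
On this task the dual-angle designs reach a 20° MAE of roughly 0.02
against the target while the normal-only design — although it fits the
0° target to MAE ≈ 0.002–0.003 — degrades to MAE ≈ 0.05 at 20°, i.e.
the dual-angle merits cut the oblique-incidence error by about half or
more. These numbers are recomputed, not quoted, by
`scripts/acceptance.R` and the test suite.

## The imaging model

`synthesize_rgb()` implements
`RGB_c(x,y) = exposure * sum_l cube(x,y,l) T(l) CSR_c(l) w_l`
with trapezoidal band weights `w_l`. Filter and camera response are both
diagonal spectral weights, so they commute — a property under test.
Exposure is set once per evaluation so that the 99th percentile of the
*no-filter* image maps to 0.95, and is then held fixed across curve
swaps; without a shared radiometric scale the swap comparison would be
meaningless. Clipping to [0, 1] happens only after exposure. The default
camera response is three smooth Gaussian-like channels peaking near
460/540/600 nm — a synthetic stand-in for a machine-vision sensor; a
measured CSR can be supplied as CSV.

## What the synthetic data emulates — and what it does not

The generator produces everything the pipeline consumes:

* **Target curves** — logistic-edged band-pass/notch/double-band shapes.
* **Known-truth stacks** — seeded random thicknesses in [30, 250] nm on
  the alternating structure, with their exact spectra, used for recovery
  experiments (optimize from a ±15 nm-perturbed start, recover the
  spectra to MAE < 0.01 — in practice ~1e-5).
* **Scenes** — 64×64 px, 41 bands (400–800 nm, 10 nm), three elliptical
  "peppers" (semi-axes 6–14 px) on a leaf background with a smooth
  multiplicative texture, flat illumination, per-object multiplicative
  jitter (sd 0.05) and additive Gaussian band noise (sd 0.01 of peak
  radiance). Pepper and leaf reflectances are Gaussian-peak-plus-red-edge
  curves constructed so that they correlate above 0.9 (near-colour in
  RGB) while a nearest-spectrum pixel classifier is essentially perfect
  on noise-free scenes: the task is solvable from spectra and genuinely
  ambiguous from broadband colour, which is the premise the filter
  design exploits.

Deliberately *not* modelled: radiative transfer, BRDF and occlusion,
camera noise and demosaicing, per-pixel incidence-angle variation across
the sensor. Passing tests therefore demonstrate the pipeline's internal
consistency and the *ordering* of designs under controlled conditions —
not absolute segmentation accuracy on real greenhouse imagery, whose
band count, labelling protocol and optics are different and unpublished.

## The segmenter and the freeze-and-swap protocol

The segmenter is a compact fully-convolutional encoder–decoder with skip
connections: 3×3 convolutions, ReLU, 2× max-pooling per encoder level,
nearest-neighbour upsampling with skip concatenation, and a 1×1 output
head; pixelwise binary cross-entropy, Adam, threshold 0.5 for binary
maps. The default is depth 2 with 8 base channels — deep enough to reach
validation mIoU above 0.95 on the synthetic scenes within ~30 seeded
epochs on one CPU, and small enough that the whole three-seed evaluation
protocol runs in minutes; both depth and width are configuration fields
when a larger network is wanted. Forward and backward passes are plain
matrix algebra (im2col convolutions), which keeps training bit-for-bit
reproducible from the seed.

The evaluation mirrors the freeze-and-swap idea: train once on RGB
synthesized with the normal-only design's 0° curve (the stand-in for a
previously manufactured filter), freeze the weights, then re-evaluate the
same network on RGB synthesized with other curves — each design's 0°
curve, its 20° s- and p-polarized curves, and the all-ones no-filter
baseline. mIoU uses k = 2 classes; classes absent from both prediction
and ground truth are skipped rather than scored 1. On the default
synthetic protocol the wide-angle design's 20° curves lose almost no
mIoU relative to 0°, the normal-only design's 20° s-curve collapses
(blue-shifted colours the frozen network never saw), and both filtered
0° curves score at or above the no-filter baseline.

## Numerical choices and degenerate inputs

* Total internal reflection, grazing-incidence zero denominators,
  perfect-reflector `M[1,1] = 0`, zero interface transmission and
  non-finite merits during line search all raise explicit errors rather
  than propagating NaNs.
* Curve resampling is linear with edge hold, clipped to the source
  range; spectral CSVs reject values outside [0, 1.5] and non-monotone
  wavelengths with line numbers.
* The unpolarized transmittance is defined as the arithmetic mean
  `(T_s + T_p)/2` — the only bounded reading, and exact at normal
  incidence where the polarizations coincide.
* Max-pooling ties break toward the first child; Adam uses the standard
  bias correction; He initialization scales with fan-in.
* Scene sizes must be divisible by `2^depth`; the generator refuses
  scenes too small for the requested ellipse axes.

## Problem sizes

Defaults used throughout the examples, tests and the acceptance script:
201-wavelength design grid, 60-layer design task, 10-layer recovery
task, 30 scenes of 64×64×41 per evaluation (18/6/6 train/val/test),
30 training epochs, three seeds for stochastic comparisons. These are
the package's own study conditions; all are parameters, not constants.

## Known limitations

* No dispersion or absorption models; indices are per-material constants.
* The substrate back surface and incoherent averaging are not modelled.
* The CSR is synthetic unless a measured one is supplied.
* Absolute mIoU values on synthetic scenes say nothing about absolute
  performance on real imagery; only design orderings are meaningful.
* The optimizer is local; different seeds can find different basins, and
  the package reports the best-of-restarts rather than claiming a global
  optimum.
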