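# widefilm

Wide-angular-tolerance thin-film optical filter design and spectral
imaging simulation, in R.

Interference band-pass filters blue-shift at oblique incidence: every
layer's phase thickness `2πnd·cos(θ)/λ` shrinks as the angle grows, so
the pass-band a camera sees at the edge of a wide field of view is not
the one it sees on-axis. For near-colour discrimination tasks — green
peppers against green leaves — that shift destroys exactly the spectral
contrast the filter was built to amplify. `widefilm` designs filters
whose transmittance stays put between normal and oblique incidence, and
quantifies what that buys a downstream segmentation network.

The package is aimed at optical-design and computational-imaging
researchers who want a fully scripted, seeded desk-scale pipeline: no
measured target curves or proprietary hyperspectral datasets are needed —
a synthetic generator stands in for both.

## What is inside

* **Transfer-matrix optics** (`transmittance_spectrum`,
  `refraction_angles`, `fresnel_interface`, `stack_matrix`, ...):
  polarized R/T spectra of lossless multilayer dielectric stacks at any
  incidence angle, vectorized over wavelength, with *exact analytic
  gradients* of transmittance with respect to every layer thickness
  (`transmittance_gradient`).
* **Dual-angle merit functions and design** (`merit1`, `merit2`,
  `merit_gradient`, `optimize_thicknesses`): with `T^θ = (T_s + T_p)/2`
  and a target curve `T*` on an N-point grid,

      Merit 1 = (1/N) Σ_λ [ (T^0_λ − T*_λ)² + (T^θ1_λ − T*_λ)² ]
      Merit 2 = (1/N) Σ_λ [ (T^0_λ − T*_λ)² + (T_p^θ1_λ − T*_λ)² + (T_s^θ1_λ − T*_λ)² ]

  minimized over layer thicknesses by L-BFGS-B under a non-negativity
  bound, with seeded initialization and restarts. A `normal_only`
  variant is the single-angle baseline.
* **Imaging simulation** (`synthesize_rgb`, `default_csr`,
  `auto_exposure`): hyperspectral cube × filter transmittance × camera
  spectral response → RGB, with trapezoidal band weights and a shared
  exposure across curve swaps.
* **Synthetic data** (`make_target_curve`, `make_known_stack`,
  `make_scene`, `make_dataset`): band-pass targets, known-truth stacks
  for recovery experiments, and two-class near-colour pepper/leaf scenes
  with ground-truth masks (reflectance correlation > 0.9, yet perfectly
  separable from spectra).
* **Segmentation evaluation** (`train_segmenter`, `swap_and_evaluate`,
  `mean_iou`, `curves_for_design`): a small encoder–decoder CNN (pure R,
  seeded, CPU) trained on one curve's RGB, frozen, and re-scored under
  swapped transmittance curves, Table-style, by mean IoU.
* **I/O and CLI**: spectral CSV, stack YAML, ENVI cubes, PNG masks, JSON
  run manifests; an umbrella `inst/cli/widefilm` script with
  `design-filter`, `gen-synthetic`, `simulate-rgb`, `train-seg` and
  `evaluate-swap` subcommands.

## Worked example

Design a 60-layer tantala/silica band-pass for 0° *and* 20°, and compare
it with a normal-incidence-only design:

```r
library(widefilm)

grid   <- default_grid()                                  # 400-800 nm, N = 201
target <- make_target_curve("bandpass", center = 550, width = 80, grid = grid)

init <- initialize_design(60, "quarter_wave", seed = 1, jitter_nm = 10)
wide <- optimize_thicknesses(init, target, merit_config("merit1", grid = grid),
                             max_iter = 500, seed = 1, restarts = 1)
norm <- optimize_thicknesses(init, target, merit_config("normal_only", grid = grid),
                             max_iter = 500, seed = 1, restarts = 1)

mae20 <- function(fit, pol) {
  sp <- transmittance_spectrum(fit$stack, 20 * pi / 180, grid)
  mae_curve(spectral_curve(grid, if (pol == "s") sp$T_s else sp$T_p), target)
}
c(normal_only_s = mae20(norm, "s"), wide_s = mae20(wide, "s"),
  normal_only_p = mae20(norm, "p"), wide_p = mae20(wide, "p"))
#> normal_only_s        wide_s normal_only_p        wide_p
#>    0.04829139    0.02139667    0.05553902    0.02284636
```

Both designs match the target well at normal incidence (the normal-only
design to MAE ≈ 0.003), but at 20° the normal-only design's error roughly
doubles the dual-angle design's: optimizing both angles at once halves
the oblique-incidence error. `autoplot(wide)` shows the merit trace;
`tidy(wide)` the per-layer thicknesses; `glance(wide)` the fit summary.

Downstream, the freeze-and-swap evaluation trains a small segmenter on
RGB synthesized through the normal-only design's 0° curve, freezes it,
and swaps in each design's 0° and 20° curves plus a no-filter baseline:

```r
ds    <- make_dataset(30, scene_spec(), seed = 1001)
model <- train_segmenter(ds$train, unpolarized_T(norm$stack, 0, grid),
                         config = seg_config(epochs = 30, seed = 1),
                         val_scenes = ds$val)
curves <- c(curves_for_design(wide, grid = grid, prefix = "wide"),
            curves_for_design(norm, grid = grid, prefix = "normal"))
swap_and_evaluate(model, ds$test, curves)
#>   curve_name     angle_deg polarization  miou
#> 1 wide_0deg              0 unpolarized   0.945
#> 2 wide_20deg_s          20 s             0.970
#> 3 wide_20deg_p          20 p             0.984
#> 4 normal_0deg            0 unpolarized   0.990
#> 5 normal_20deg_s        20 s             0.551
#> 6 normal_20deg_p        20 p             0.780
```

The frozen network barely notices the wide-angle design's 20° curves,
while the normal-only design's blue-shifted 20° s-curve costs it ~0.44
mIoU — the angular tolerance survives all the way to the downstream
task.

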