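# morphoforce

Tissue-scale forces during morphogenesis — for example the medial apposition
of the neural folds as the embryonic neural tube closes — can be read out from
elastic hydrogel cylinders photo-printed between the moving tissues. Because
the hydrogel behaves as a linearly elastic (neo-Hookean) solid over the
working range, the cylinder is a calibrated spring: its mediolateral narrowing
δ reports the compressive force as

    F = k · δ,        k = α · H · (t/D)³ · E

where `H` is the cylinder height, `D` its outer diameter, `t` the wall
thickness (all µm), `E` the hydrogel Young's modulus (kPa; with these units
`k` is in nN/µm), and `α` a dimensionless constant calibrated by least
squares against a finite-element parameter sweep (shipped default
`α = 7.718`). Typical sensors resolve nano-newton forces and the picojoule
elastic energies stored during fold apposition.

`morphoforce` is aimed at developmental-biomechanics groups using printed
elastic force sensors. It implements the whole chain in one package:

* **materials** — neo-Hookean constitutive helpers, Young's modulus from AFM
  indentation curves (pyramidal Hertz fit, ν = 0.5) and from uniaxial
  stress–strain records;
* **ring FEM** — geometrically nonlinear plane finite elements (bilinear
  quadrilaterals with incompatible bending modes; frictionless penalty
  contact against rigid surfaces) for the cylinder cross-section, plus a
  corotational beam solver for bar- and V-spring-shaped sensors;
* **calibration** — the (H, D, t, E) stiffness sweep and the least-squares
  fit of `α`;
* **imaging** — drift registration (translation or rigid), Otsu/fixed
  thresholding, largest-component selection and bounding-rectangle width of
  time-lapse TIFF stacks;
* **inference** — width → strain → force → stored elastic energy → 60-min
  impulse → ATP equivalents, plus cohort means with 95% CIs and two-group
  tests;
* **synthetic data** — seeded generators for deformation trajectories,
  embryo cohorts, rendered movies and AFM curves, each emitting noise-free
  ground truth, so every stage is testable without microscope data.

## Worked example

A sensor printed with `H = 20`, `D = 180`, `t = 15` µm at `E = 80` kPa, and a
width trace (packaged, synthetic) sampled every 30 min:

```r
library(morphoforce)

geom <- cylinder_geometry(H = 20, D = 180, t = 15)
k <- predict_stiffness(geom, E_kPa = 80)   # 7.146296 nN/um

trace <- read_trace_csv(system.file("extdata", "synthetic_trace.csv",
                                    package = "morphoforce"))
prof <- force_profile(trace, k = k)
prof
#> force_profile: 17 timepoints, peak |force| 102.9 nN, final energy 0.741 pJ,
#> max 60-min impulse 4545 nN min
head(as.data.frame(prof), 4)
#>   time_min strain_pct force_nN energy_pJ valid
#> 1        0   0.000000  0.00000 0.0000000  TRUE
#> 2       30   3.888889 50.02407 0.1750843  TRUE
#> 3       60   5.888889 75.75074 0.4014789  TRUE
#> 4       90   6.944444 89.32870 0.5583044  TRUE
atp_equivalent(tail(prof$energy, 1))
#> [1] 7409280
```

Reading: the sensor narrows by ~3.9% within the first half hour (50 nN), then
saturates near 8% strain — about 103 nN of compressive force, with 0.74 pJ
stored elastically (the energy ~7 × 10⁶ ATP molecules could supply). The
`valid` flag marks points inside the ±20% strain range where the linear gauge
is trusted; the maximum 60-min impulse (force generated in the best hour ×
60 min) summarizes the force-generation rate.

Calibrating `α` yourself instead of using the shipped constant:

```r
sweep <- run_sweep()       # 3^4 grid over H 20-100, D 140-220, t 5-25 um, E 5-80 kPa
fit_alpha(sweep)
#> alpha_fit: alpha = 7.7357 (absolute LS, n = 81), R^2 = 0.9999, ...
```

A thin command-line wrapper for shell pipelines lives at
`inst/cli/morphoforce` (`infer-force`, `extract`, `simulate-ring`,
`calibrate-alpha`, `fit-afm`, `fit-uniaxial`, `cohort`, `synth`), driven by
YAML/JSON configs via `validate_config()`/`mf_run()`.

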