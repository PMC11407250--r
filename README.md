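# fetalnirs

Simulation-based sensitivity analysis for **transabdominal fetal pulse
oximetry**: can near-infrared light launched on the maternal abdomen sense
the fetal brain, and what probe geometry does it take?

The package is aimed at biomedical-optics researchers designing NIRS probes
for fetal monitoring. It provides, as tested building blocks and as a
config-driven pipeline:

* **Synthetic maternal–fetal phantoms** — layered abdominal wall (fat,
  muscle/uterus, amniotic fluid) over a shelled spherical fetal head
  (scalp, skull, CSF, brain), meshed with structured tetrahedra, optionally
  bent onto a cylindrical abdomen. Occiput-anterior (brain at 30 mm) and
  occiput-posterior (45 mm) reference configurations.
* **Tissue optics** — chromophore-mixture absorption
  μa = [HbT]·StO₂·ε_HbO + [HbT]·(1−StO₂)·ε_Hb + V_water·μa,water + …,
  power-law scattering μs′ = a·(λ/500 nm)^(−b), arterial/venous fetal
  compartments with a 5% systolic volume pulse in brain and muscle.
* **Forward model** — continuous-wave diffusion equation
  −∇·(κ∇φ) + μa φ = q with Robin boundaries, P1 finite elements, sparse
  Cholesky solves; 10 × 10 mm integrating detectors.
* **Sensitivity** — adjoint absorption Jacobians J_ij = ∂Φ_i/∂μa,j,
  distance-group normalized sensitivity maps, fetal-brain channel ranking.
* **Imaging sensitivity** — flat-field analysis: uniform 1% μa
  perturbation, Moore–Penrose reconstruction with spatially variant
  regularization, rule-of-thumb feasibility classification.
* **Pulse & noise** — ΔOD = log₁₀(Φ_diastole/Φ_systole), detector dynamic
  range Φ_d/(Φ_d−Φ_s), and a distance-dependent noise model
  k(r) = 0.0024·e^(0.0236·r) with 480-beat averaging.

See `vignettes/fetalnirs-methods.Rmd` for the model, its assumptions and
the numerical design decisions.

## Worked example

An occiput-anterior phantom with the default 6 × 6 optode grid
(100 × 70 mm) at 730 nm:

```r
library(fetalnirs)

spec <- oa_phantom_spec()
spec
#> phantom_spec: brain depth 30.0 mm (fat 10.0 + muscle 10.0 + fluid 2.5 + shells 7.5)
#>   head radius 45.0 mm, domain 150 x 120 x 55 mm, edge 5.0 mm, curved R=150 mm

mesh <- build_phantom(spec)
round(surface_to_label_distance(mesh, "fetal_brain"), 1)   # realized depth
#> [1] 30

layout <- build_probe_layout(mesh)            # 18 sources, 18 detectors
channels <- group_channels(select_channels(layout))
attr(channels, "groups")
#>   group_id   label lower upper  NM
#> 1        1   20-40    20    40  70
#> 2        2   40-60    40    60 102
#> 3        3   60-80    60    80  48
#> 4        4  80-100    80   100  52
#> 5        5 100-120   100   120  22

round(100 * noise_std(c(20, 60, 120)), 2)     # noise model, percent
#> [1] 0.38 0.99 4.08

cfg <- run_config(phantom = spec, wavelengths = 730,
                  outdir = "readme_run", seed = 1)
man <- run_pipeline(cfg)
man
#> fetalnirs run: seed 1, 294 channels, 10.8 s
#> outputs: channels.csv, metrics.csv, rankings.csv, summary.csv, feasibility.json, config.json
```

The per-group summary over the ten best fetal-brain channels shows why
long source–detector separations are required (sensitivity is the brain
share of each channel's normalized Jacobian; ΔOD and dynamic range include
the distance-dependent noise averaged over 480 beats):

```r
s <- read.csv("readme_run/summary.csv")
subset(s, group %in% c("20-40", "100-120"),
       c(group, sensitivity_mean, delta_od_mean, max_fluence_mean,
         dynamic_range_mean))
#>     group sensitivity_mean delta_od_mean max_fluence_mean dynamic_range_mean
#> 1   20-40           0.0708     -6.51e-06         1.63e-03               4007
#> 5 100-120           2.0214      3.54e-04         1.66e-05               2611
```

Short channels (20–40 mm) carry ~30× less brain sensitivity and their
noisy pulse signal is indistinguishable from zero, while 100–120 mm
channels see the brain and retain a positive pulse ΔOD. The rule-of-thumb
feasibility report agrees:

```r
f <- jsonlite::read_json("readme_run/feasibility.json", simplifyVector = TRUE)
f[f$group %in% c("20-40", "100-120"),
  c("group", "jac_max_brain", "ff_max_brain", "feasible")]
#>     group jac_max_brain ff_max_brain feasible
#> 1   20-40       0.00066        0.013    FALSE
#> 5 100-120       0.03409        0.207     TRUE
```

i.e. the normalized Jacobian at the fetal brain exceeds the 1% threshold
only for the 100–120 mm group. Swapping in `op_phantom_spec()` (brain at
45 mm behind fetal soft tissue) collapses the best channel score by about
two orders of magnitude — the deep-fetus configuration is not measurable
with this setup.

A command-line front end covers the same flow:

```sh
Rscript exec/fetalnirs run --config cfg.json --seed 1 --outdir out/
Rscript exec/fetalnirs phantom build --outdir out/
```

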