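---
title: "Simulating depth sensitivity for transabdominal fetal pulse oximetry"
author: "fetalnirs developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating depth sensitivity for transabdominal fetal pulse oximetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Transabdominal fetal pulse oximetry asks whether near-infrared light launched
on the maternal abdomen can detect the fetal cardiac pulse — and ultimately
fetal brain oxygen saturation — through 25–45 mm of intervening maternal
tissue and amniotic fluid. `fetalnirs` provides a simulation pipeline to
answer the design questions that precede any hardware build: which
source–detector (SD) separations carry sensitivity to the fetal brain, how
much optical density modulation the fetal pulse produces at the detector,
what detector dynamic range that requires, and how measurement noise that
grows with SD distance erodes the signal.

Because patient-specific MRI meshes are not distributable, the package ships
a parametric synthetic phantom that emulates the relevant anatomy instead of
reproducing any individual subject.

## The phantom

`phantom_spec()` describes a layered abdominal wall over an embedded fetal
head, meshed with a structured Freudenthal (six-tetrahedra-per-cell)
triangulation:

* maternal fat (default 10 mm) and merged muscle/uterine wall (10 mm);
* an amniotic fluid gap (2.5 mm) — fluids are water-absorbing and almost
  non-scattering (μs′ = 0.1 cm⁻¹, n = 1.33);
* a spherical fetal head (radius 45 mm) with concentric scalp-muscle (2 mm),
  skull (3 mm) and CSF (2.5 mm) shells around the brain.

The default, `oa_phantom_spec()`, puts the brain boundary 30 mm beneath the
surface — the occiput-anterior situation. `op_phantom_spec()` emulates the
occiput-posterior presentation: the maternal wall is unchanged, but 15 mm
of additional fetal soft tissue sits in front of the skull (the fetus faces
the abdomen), placing the brain at 45 mm. Two alternatives were rejected
after measurement. Widening the amniotic fluid gap costs only a factor ~3
in brain sensitivity, because the fluid is nearly transparent at these
wavelengths. Thickening the whole maternal wall attenuates the superficial
sensitivity peak that normalizes every map by the same factor as the brain
signal, so *normalized* brain sensitivity barely moves. Only extra tissue
between an unchanged wall and the brain reproduces the one-to-two-order
collapse that distinguishes the presentations; this is the package's own
modelling choice for a geometry the anatomy literature describes only
qualitatively.

Curvature: the slab can be bent onto a cylinder (default radius 150 mm) to
mimic the abdomen. The bending map preserves arclength on the scanned
surface and radial depth, so optode spacing and layer depths keep their
nominal values; the head sphere is defined in the unbent frame and is
therefore slightly distorted after bending, with on-axis depths preserved
exactly. A flat slab (`abdomen_curvature_radius = NULL`) is available for
analytic validation.

Element labels are assigned by centroid, so tissue interfaces are quantized
at the mesh edge length (default 5 mm; tests verify the realized
surface-to-brain distance to within one edge length). The mesh generator is
fully deterministic; the `seed` argument exists for forward compatibility
with jittered meshing and is recorded in run manifests.

## Optical properties

Tissue absorption follows the chromophore mixture model

μa(λ) = [HbT]·StO₂·ε_HbO(λ) + [HbT]·(1−StO₂)·ε_Hb(λ)
      + V_water·μa,water(λ) + V_fat·μa,fat(λ) + V_melanin·μa,melanin(λ)

with concentrations in µM and extinction coefficients in cm⁻¹µM⁻¹ (the
ln 10 factor folded in). Fetal tissues split [HbT] into arterial (25%) and
venous (75%) compartments with separate saturations (SaO₂ = 50%,
SvO₂ = 40%); the cardiac pulse is modelled as a 5% systolic volume increase
of the *arterial* compartment in fetal brain and scalp muscle only — skull
and maternal tissues never pulse. Reduced scattering follows the power law
μs′ = a·(λ/500 nm)^(−b). All per-tissue constants live in
`default_tissue_params()`.

The extinction/absorption spectra are shipped as a 1-nm table
(`inst/extdata/chromophores.csv`) spline-interpolated from 10-nm anchors
after the standard public compilations (Prahl hemoglobin; Hale & Querry
water; van Veen fat; melanosome power law). The anchors are rounded
reference values adequate for structural conclusions (orderings, ratios,
linearity); no absolute absorption value in this package should be read as
metrology, and no test asserts one.

The simulated wavelength set is 730–850 nm in 20 nm steps (seven
wavelengths).

## Forward model

Continuous-wave photon transport is modelled by the diffusion equation
−∇·(κ∇φ) + μa φ = q, κ = 1/(3(μa+μs′)), discretized with linear (P1)
tetrahedral finite elements and the Robin boundary condition
φ + 2Aκ ∂φ/∂n = 0. The internal-reflection coefficient A comes from the
Groenhuis/Keijzer polynomial in the local refractive index; a constant
override (A = 1) serves matched-boundary analytic tests. Sources are
isotropic points one transport mean free path (1/μs′) beneath the surface
anchor, spread onto the enclosing element with barycentric weights and
normalized to unit power. The sparse SPD system is solved by Cholesky
factorization (cached per optical state, reused across all sources and
adjoints) plus one iterative-refinement step; solves are rejected above a
1e−10 relative residual.

Two numerical caveats are deliberate:

* **Fluid layers.** The diffusion approximation is formally invalid in the
  almost non-scattering amniotic fluid/CSF (μs′ = 0.1 cm⁻¹). We solve
  through them as-is — the same choice standard FEM NIRS toolboxes make —
  so absolute fluences in/beyond fluid carry unquantified model error.
* **No discrete maximum principle.** P1 fields can oscillate slightly
  negative near the point-source singularity and in the deep far field
  (~1e−3 of peak on coarse test meshes). Tests therefore assert positivity
  and monotonicity on the resolved part of the field, and Jacobian
  non-positivity up to that leakage.

Large detectors are 10 × 10 mm squares around each detector anchor in the
surface's parametric frame, sampled on a uniform grid with spacings < 0.5 mm
(default 0.4 mm); surface nodal fluence is linearly interpolated via the
surface triangles and the patch fluence is Φ = Δx·Δy·Σφᵢ. The quadrature is
exact for constant fields (weights sum to 100 mm²) and agrees with a
0.1 mm grid to better than 1% on solved fields.

## Sensitivity analysis

The absorption Jacobian J_{ij} = ∂Φᵢ/∂μa,j (channel i, node j) is computed
by the adjoint method. The absorption mass term is assembled from a P1
nodal interpolation of μa (volume-weighted element-to-node average), which
makes the adjoint product the *exact* derivative of the discrete forward
map — the central-finite-difference oracle agrees to ~1e−6 relative, far
inside the 0.5% test tolerance. κ is held fixed under μa perturbation, the
standard CW convention.

Channels are grouped by SD distance (20–120 mm in 20 mm bins, half-open
with the last bin closed). Per group, the total normalized sensitivity map
is the channel-summed Jacobian divided by its maximum absolute value. A
channel's fetal-brain score is Σ|J_{ij}| over brain nodes divided by the
channel's own peak |J| — the brain mass of the channel's normalized
sensitivity map. The normalization matters: raw |J| row mass scales with
the channel's overall transmission, so a 20 mm channel would outrank a
110 mm one simply because it detects vastly more light, not because it
senses the brain. Dividing by the row peak removes the transmission factor
and makes scores comparable across distances and phantoms; within one
distance group both definitions give the same ordering (the raw variant
remains available). Rankings break ties by shorter distance, then lower
channel id.

## Flat-field imaging sensitivity

A uniform 1% μa increase is forward-modelled, per-channel difference data
∂Φ = Φ(baseline) − Φ(perturbed) (optionally noisy) are formed, and a
Moore–Penrose inversion with spatially variant regularization recovers
δμa. With D = diag(JᵀJ) + α, α = 10⁻²·max diag(JᵀJ), and the channel-space
analogue E, β, the implementation applies the diagonal inverse-square-root
operators consistently on both sides:

δμa = D^(−1/2) J̃ᵀ (J̃J̃ᵀ + I)⁻¹ ∂Φ̃,  J̃ = E^(−1/2) J D^(−1/2),
∂Φ̃ = E^(−1/2) ∂Φ.

The source equations for this construction are typographically ambiguous
(the measurement-scaling line is self-referential as printed, and "L" is
used both for the operator and its inverse); the reading above is the
standard one that normalizes diag(J̃J̃ᵀ) ≈ 1 and keeps the inversion
well-posed, and the package treats it as a design decision. Reconstruction
is per channel (one-row J), then summed and normalized within each SD
group. A dense closed-form transcription of the same equations is kept as a
test oracle at 1e−10 relative agreement.

Feasibility follows the field's rule of thumb: a region is measurable when
its normalized Jacobian exceeds 1% and reconstructable when its normalized
flat-field value reaches the 1–10% band (`classify_feasibility()`,
thresholds configurable).

## Pulse metrics and noise

ΔOD = log₁₀(Φ_diastole/Φ_systole) (base configurable; base 10 is the
optical-density convention) and DynamicRange = Φ_diastole/(Φ_diastole −
Φ_systole), linked by DR = 1/(1−10^(−ΔOD)). Note the subtraction amplifies
floating-point error by a factor ~DR, so the identity holds to DR-scaled
machine precision — the tests use 1e−9 relative.

Measurement noise is multiplicative Gaussian with fractional standard
deviation k(r) = 0.0024·e^(0.0236·r) (r in mm): about 0.4%, 1% and 4% at
20, 60 and 120 mm. Noisy metrics average 480 independent realizations per
state (4 minutes of a 2 Hz fetal heart rate) before forming ΔOD and DR;
draws are independent across channels, states and repetitions (the minimal
assumption — no correlation structure is specified by the underlying
model). At long distances the averaged systolic fluence can exceed the
diastolic one, in which case the dynamic range is reported as `Inf` with an
overflow flag rather than a spurious number.

## What the synthetic phantom does and does not establish

The generator reproduces the *structure* of the problem: layer ordering and
thicknesses, fluid transparency, a curved abdomen, a shelled fetal head at
configurable depth, a 6 × 6 optode grid over ~100 × 70 mm with chord-metric
channel selection (20–120 mm). It does not reproduce patient-specific
anatomy: tissue interfaces are smooth and concentric, lateral heterogeneity
is absent, and the meshes are 10–100× coarser than MRI-derived ones. Green
tests on this phantom therefore establish internal correctness (oracles,
identities, orderings, order-of-magnitude contrasts) — e.g. that 100–120 mm
channels dominate brain sensitivity at 30 mm depth and that 15 mm of extra
tissue depth costs one to two orders of magnitude — but not absolute
channel counts, fluence values or sensitivity percentages of any real
anatomy.

## Numerical choices worth knowing

* Chord (Euclidean) distances between optodes, not geodesic; on the default
  curvature the difference is below 1%.
* Distance bins are half-open [lo, hi) with the last bin closed at 120 mm.
* Checkerboard source/detector assignment on the grid maximizes distance
  diversity; only the 18/18 split is prescribed.
* Forward accuracy: on a homogeneous cube with μa = 0.05 cm⁻¹,
  μs′ = 3 cm⁻¹ the refined (~30k-node, 3.5 mm) mesh matches the
  infinite-medium Green's function within 10% for r ∈ [10, 40] mm away from
  boundaries, improving from ~50% at 7 mm. Resolving the exponential decay
  requires the edge length to stay below the attenuation length 1/μeff —
  at stiffer (more absorbing) properties a desk-scale mesh cannot hold the
  10% band, which bounds what the coarse pipeline meshes can promise for
  absolute values.
* All randomness flows through R's RNG; pipelines `set.seed(seed)` once and
  record the seed in the manifest, making every output file checksum
  reproducible.
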