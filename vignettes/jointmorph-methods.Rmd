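---
title: "jointmorph: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{jointmorph: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`jointmorph` is an analysis pipeline for studying how muscle-contraction
biophysical stimuli pattern the morphogenesis of the embryonic chick knee.
It compares a **normal** regime (dynamic flexion/extension contraction
cycles) with a **rigid paralysis** regime (sustained tetanic co-contraction
of all muscles at reduced force), and separately quantifies the shape and
proliferation phenotype of immobilisation. This vignette documents the
models and the deliberate design decisions; the numbered scripts under
`analysis/` run the two experiment recipes end to end.

All units are mm, kPa, seconds and micro-newtons for muscle forces
(permeability in mm^4 N^-1 s^-1).

## 1. Synthetic knee phantoms

`generate_joint_phantom()` builds a binary voxel volume of the developing
knee: a distal femur whose two box-shaped condyles flank a
rectangular-profile intercondylar fossa (open on the ventral side), a planar
interzone gap, and proximal tibiotarsus and fibula blocks. The phantom is a
*box approximation*: every one of the twelve morphometric lengths is a
directly constructed dimension snapped to whole voxels, so each generated
volume carries exact ground truth for measurement validation. The price is
that the outlines are rectilinear rather than organically curved; the
measurement operators never exploit this, as the randomised recovery sweep
includes deformed variants.

`shape_simplification` in [0, 1] moves the phantom from a control-like
morphology (0) to the immobilised phenotype (1): the fossa narrows (43% at
full effect), condyle heights shrink (16%), the interzone thins (30%) and
the epiphyses narrow (~19%) — shrink factors chosen once, at design time, to
mirror the strongest reported immobilisation effect sizes of the modelled
system. `random_phantom_params()` adds multiplicative log-normal jitter
(default CV 4%) for specimen-to-specimen variation.

```{r phantom}
library(jointmorph)
vol <- generate_joint_phantom(phantom_params())
vol$ground_truth   # twelve exact lengths, keyed i..xi
```

## 2. Morphometric measurements

`measure_knee()` measures the twelve lengths on virtual sections located by
`locate_section_planes()`: a frontal midline plane through the condylar
centroid row, a ventral-offset frontal plane, and a transverse epiphyseal
plane. Measurements iv and v (condyle heights) use the *fossa-floor datum*:
the highest per-column minimum-z of the femur, i.e. the distal shaft
surface, from which heights are read to the condyle apices. Plane location
is index-based and therefore exactly equivariant under voxel translations.

On the default (unjittered) phantom all twelve measurements reproduce
ground truth exactly; over randomised sweeps the contract is recovery
within one voxel.

## 3. Cartilage outlines and rigid overlay

`extract_outline()` anti-aliases the femoral midline section with a small
box filter and traces the 0.5 iso-contour, giving a sub-voxel polygon.
Anchors are fitted per outline: principal-axis lines through the medial and
lateral side bands and the intercondylar fossa midpoint.
`overlay_outlines()` mirrors the manual overlay procedure — a *rigid*
transform (rotation + translation, no scaling) rotates the mean side-line
direction onto the proximo-distal axis and translates the fossa midpoint to
the origin — then reports sector widths on a scanline just distal of the
fossa floor. Alignment is idempotent to floating-point precision.

## 4. Poroelastic finite-element model

`solve_poroelastic()` implements quasi-static linear Biot poroelasticity in
plane strain on linear triangles (u–p mixed form, equal-order
interpolation), with incompressible constituents (zero storage) and
isotropic permeability. Equal-order u–p pairs are not inf–sup stable, so a
pressure-Laplacian stabilisation acting on the *pressure increment* is
added with scale `stab_beta * h^2 / (lambda + 2G)`; it vanishes at steady
state and does not perturb the drained limit. Time integration is backward
Euler; the sparse system is factorised once (`Matrix::lu`) and reused over
steps. Every retained snapshot is checked against the discrete equilibrium
residual.

Verification (reproduced in `analysis/04_solver_verification.R` and the
test suite):

* **Patch test** — a prescribed linear displacement field is reproduced
  with constant stress to ~1e-15 relative error.
* **Terzaghi consolidation** — the 1D pore-pressure profile matches the
  analytic series to 0.45% max relative error at time factors 0.1/0.3/0.5
  on a 40x4 strip, converging monotonically under mesh/time refinement
  (0.90% on 20x2, 0.22% on 80x8).

### Materials

Default constants are configurable placeholders on the embryonic-tissue
kPa scale, not measurements: cartilage E = 1 kPa, interzone E = 0.1 kPa,
Poisson ratio 0.3, Biot coefficient 1, interzone 10x more permeable than
cartilage. The absolute permeability scale (cartilage k = 300 mm^4 N^-1
s^-1) is chosen so the consolidation diffusion length `sqrt(c_v t)` at the
mid-contraction reporting time (0.25 s) is comparable to the joint-region
half-depth (~0.3 mm): the section is then at *mid-consolidation* when
reported, the regime in which interstitial-flow patterns are informative.
At near-undrained scales the bonded stiff rudiment faces squeeze the soft
interzone so that pressure concentrates at the interfaces and the mid-band
ordinal structure is unobservable.

### Mesh and boundary conditions

`phantom_to_mesh()` resamples the frontal section on a structured grid and
splits each cell into two right triangles (minimum interior angle 45° by
construction). The gap between facing rudiment surfaces (up to
`interzone_max`) is filled with interzone elements. Node sets: fixed
proximal femoral and distal tibiotarsal cuts, four muscle attachment
patches (flexors on the mid-tibiotarsus sides, extensors at the femoral
capsular-condensation level), and the `capsule` set — the external margin
of the interzone — which the pipeline *seals* against drainage so that
interzone fluid exits through the cartilage, as across a joint capsule.
All other external surfaces drain freely.

### Muscle load regimes

`default_muscle_table()` is a documented fixture, not a measurement: two
flexors (250 uN each) pulling obliquely with a strong lateral component,
and two weaker extensors (125 uN each) pulling medially. Flexion and
extension each activate one group at full magnitude with a ramped cycle;
the snapshot is taken mid-cycle (half of peak-load time). **Paralysis**
applies *every* muscle simultaneously and continuously at 75% of its
normal peak — rigid tetanic co-contraction by immobilisation — and is run
to steady state. Because the single-group regimes bend the joint while
co-contraction balances the transverse components, paralysis spreads
contact over both condyles: tension drops and the femoral field becomes
predominantly compressive.

## 5. Stimulus summaries and regime contrast

Five element fields are summarised: Von Mises stress, maximum/minimum
principal stress, pore pressure, and Darcy fluid-velocity magnitude.
`default_probe_regions()` defines eight anatomical regions: the
fossa-adjacent cartilage, dorsal/ventral portions of both condyles, a
patella-side interzone region, and the interzone sub-layers — the
*chondrogenous layers* (interzone elements within 0.025 mm of a cartilage
interface) and the *intermediate layer* (remaining mid-band).

`compare_regimes()` evaluates the regime contrast at the *normal-regime
peak*: region means are taken per phase and the maximum over
flexion/extension is compared (the paralysis regime has a single steady
phase). Its flags assert that, on the default configuration:

* dynamic stimulation amplitude is identically zero under paralysis;
* the fossa-adjacent Von Mises peak is present in both regimes;
* peak femoral tension under paralysis is strictly below mid-flexion's;
* the paralysed *distal femur* (elements distal of the fossa floor, the
  field of view of the section comparisons) is predominantly compressive
  (area fraction with compressive minimum principal stress and near-zero
  maximum principal stress >= 0.7);
* in the normal regime, chondrogenous-layer fluid velocity and
  intermediate-layer pore pressure both exceed the interzone-wide
  background mean.

```{r stimuli}
res <- run_stimuli_experiment(default_config())
res$report
```

## 6. Statistical stages

* `oneway_anova()` — the per-measurement two-group one-way ANOVA
  (equivalently the squared pooled-variance t-test), with percent
  reduction relative to control. Verified against a brute-force
  sums-of-squares decomposition to 1e-10.
* `fit_binomial_glmm()` — logistic-link binomial mixed model for the
  nested proliferation counts (sections within individuals), Laplace
  approximation via `lme4::glmer`. The treatment effect is converted to
  proliferating cells per 1000 at the control-arm fitted baseline. Both a
  Wald z reference and a small-sample t reference with individual-level
  degrees of freedom (`2 * min(individuals per arm) - 2`) are reported; at
  the default design size (3 per arm) the Wald test is anti-conservative
  (~16% type-I error in calibration) while the t reference achieves the
  nominal 5%, so the t reference is the recommended test at this size.
* `generate_proliferation_counts()` — the nested count simulator with
  per-region baselines, individual and section random intercepts, and a
  treatment effect specified per-1000 or in log-odds.

## 7. Reproducibility

Every stochastic stage derives its stream from the configuration seed;
`run_stimuli_experiment()` consumes no random numbers at all. Repeat runs
with the same configuration produce byte-identical CSV/JSON outputs, and
all output tables carry units in their headers.
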