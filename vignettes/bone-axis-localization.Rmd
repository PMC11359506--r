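---
title: "Locating the femur axis in a thigh by time-differential EIT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating the femur axis in a thigh by time-differential EIT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Robotic knee-replacement systems need the spatial position and orientation
of the femur's central axis. The established solution — optical trackers
screwed into the bone — creates weak spots and risks fractures. This
package studies, entirely in simulation, whether surface electrical
measurements can replace the pins: a belt of 16 electrodes around the
thigh injects small alternating currents and measures the resulting
boundary voltages, and the femur is located from the reconstructed
conductivity contrast between bone (0.02 S/m cortical, 0.002 S/m marrow at
100 kHz) and muscle (0.37 S/m).

Because absolute electrical impedance tomography is extremely sensitive to
geometric model errors, the pipeline uses the *time-differential* (DEIT)
formulation: it reconstructs the conductivity *change* between two states.
The measured state `s1` is the subject's thigh (here: a simulated
phantom); the reference state `s0` is a *digital boneless twin* in which
bone and marrow conductivities are replaced by muscle. Only the voltage
difference `dV = V1 - V0` enters the reconstruction, so model errors
common to both states cancel.

## Pipeline

1. **Phantom** (`build_phantom()`): structured tetrahedral mesh of a
   cylinder (verification geometry, concentric untilted bone) or of a
   "realistic" cross-section obtained by a smooth planar deformation of
   the cylinder — anisotropic scaling (1.25/0.85), seeded low-order
   harmonic boundary perturbations, and a boundary-preserving interior
   shift that moves the bone about 12 mm off-centre, mimicking a real
   thigh where the femur is not central. Compartments: skin (2 mm,
   0.065 S/m), subcutaneous fat (8 mm, 0.03 S/m), muscle, intramuscular
   fat inclusions (realistic shape only), cortical bone (15 mm radius),
   marrow (7 mm). Ground truth is the marrow-centre line, mapped through
   the deformation.
2. **Forward solves** (`solve_forward()`): complete electrode model on P1
   tetrahedra, 16 electrodes of nominal 7 mm diameter at the mid-plane
   plus a common-ground patch, opposite-pair drive at 10 mA, 100 kHz,
   contact impedance 100 Ohm cm^2. For each of 16 patterns, 13
   differential voltages between consecutive non-driving electrodes
   (208 measurements). The reference voltages `V1` are simulated on a
   finer mesh, the boneless voltages `V0` and the sensitivity matrix on an
   independently generated coarser inverse mesh, so the inverse problem
   never sees its own discretization (no inverse crime).
3. **Reconstruction** (`reconstruct_delta_sigma()`): one-step linearized
   Tikhonov problem `|| dV - J ds ||^2_W + lambda^2 || L ds ||^2` with
   `L` the combinatorial graph Laplacian of the inverse-mesh
   face-adjacency graph, `W = I`, `lambda = 0.00007`, solved by plain
   conjugate gradients on the normal equations (tolerance 1e-8, at most
   2000 iterations).
4. **Segmentation** (`compute_bin_partition()`, `grow_clusters()`,
   `filter_clusters()`): electrode-proximal elements (vertex within 14 mm
   of an electrode centre) are removed; the sorted values are split into
   15 bins around a fitted flat background band; face-connected region
   growing over bins 1–7 (bin 8 forms a deliberate gap, bins 9+ are
   background or positive); clusters smaller than 64 elements that touch
   the outer surface or an electrode are discarded.
5. **Axis fit** (`trim_outliers()`, `initial_axis_svd()`,
   `fit_cylinder()`, `select_bone_cluster()`): per cluster, values outside
   mean ± 1.9 SD are trimmed; the SVD of the centred element centres gives
   the initial centre/axis; a cylinder of radius `r0 = 1.5 cm` is fitted
   by bounded L-BFGS-B with parabolic axial weights; the cluster with the
   largest axial extent is taken as the femur, ties (within 10 %) broken
   by the lower mean conductivity difference, then by the larger value
   range.
6. **Evaluation** (`compute_deviation()`): positional deviation is the
   in-plane distance between the two axes' intersections with the
   electrode plane; angular deviation the folded angle between them.

```{r}
library(eitaxis)
study <- run_study(seed = 1)
study
autoplot(study)
```

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `lambda` | 7e-5 | regularization weight of the Laplacian smoothness prior |
| `amplitude` | 10 mA | drive current (checked against the frequency-dependent safety limit) |
| `frequency` | 100 kHz | only frequency with tabulated tissue conductivities |
| `contact_impedance` | 0.01 Ohm m^2 | complete-electrode-model contact impedance |
| `mesh densities` | 11 mm / 16 mm | simulation / inverse target element size |
| `b_max` | 7 | highest bin considered bone-like |
| `min_cluster_size` | 64 | discard threshold for surface-touching clusters |
| `r0` | 15 mm | radius of the fitted cylinder (the bone-shaft scale) |

## Numerical and design choices

* **Meshing.** No tetrahedral meshing library is available to R, so the
  package uses a structured mesher: concentric node rings (snapped to the
  compartment radii) are triangulated by circular merge, extruded along z
  on a graded grid, and each prism is split into three tetrahedra with
  face diagonals chosen from the smallest global vertex index — a rule
  that depends only on the shared face, which guarantees a conforming
  mesh. Conformity is property-tested.
* **Matched electrode and shell discretization.** The outer-ring node
  counts, the z grid and hence the electrode patches and the thin
  skin/fat shell elements are *identical* for every mesh of the same
  geometry, independent of the interior density. Without this, the
  discretization error of the 2 mm skin shell enters `dV` as structured
  noise several times larger than the bone signal; with it, the shell
  error cancels exactly between the two states while the interior meshes
  remain independent.
* **Electrode patches** are node-anchored 3x3 blocks on the lateral
  surface, symmetric about the electrode plane. The nominal 7 mm diameter
  is metadata; the modelled patch is resolution-limited (about 9-14 mm at
  the default densities). The common ground is a lateral patch well below
  the belt, held at zero potential; it gauge-fixes the system and carries
  the return current of the 16 single-ended basis solves from which all
  drive and measurement fields are superposed.
* **Conjugate gradients, unpreconditioned.** The normal-equations system
  is dominated by the rank-208 data term; the Laplacian penalty at
  `lambda = 7e-5` is weak. Plain CG started at zero builds the solution
  in the data term's dominant subspace first, which acts as a useful
  additional spectral filter on this under-determined problem; the
  iteration cap is part of the method's definition here, and preliminary
  experiments with Jacobi preconditioning produced distinctly worse
  iterates. The regularization parameter is only meaningful relative to
  the scaling of `J` and `dV` (SI volts and S/m here); with a different
  unit convention the same printed value implies a very different
  effective smoothing.
* **Flat-band selector.** The slope threshold for the flat background
  band is `(first slope + last slope)/2 * 0.002 * N0/N` with
  `N0 = 230000`; the band is made contiguous between the first and last
  sub-threshold slope (each lag-100 slope is taken to cover the 100
  samples it spans). The root-mean-square deviation of the band from a
  line anchored at its median sets the guard offset of the bin edges — an
  RMS is the only dimensionally consistent reading of a squared quantity
  used as an interval offset. Values outside the outermost edges are
  clamped into bins 1/15 so every retained element can be tested against
  `b_max`.
* **Outlier trim direction.** The 1.9-sigma rule is applied as standard
  outlier rejection (discard *outside* the band); the literal inequality
  would delete the cluster bulk and keep only its extremes.
* **Cylinder-fit weights.** The axial weight profile is a parabola in
  `zeta - mean(zeta)` with curvature `1/(4f)` set by the mesh extent and
  vertical shift `h` set by the electrode vertex heights. The package's
  default profile places the parabola's apex as a *maximum* at the
  electrode plane (`w = max(0, 1 - (.)^2/4f) + h`), down-weighting
  off-plane points, which is where the reconstruction is least reliable —
  the stated purpose of the weighting. The literal profile, whose apex is
  a minimum so that weight *grows* off-plane, is available via
  `invert_weights = FALSE`; empirically it stabilizes the axis direction
  on near-isotropic clusters but drags the in-plane position towards the
  cluster ends.
* **Frozen weights, bounded refinement.** The weights are computed once
  from the initial axis: refreshing them during optimization makes the
  objective degenerate (an axis perpendicular to the cluster sends every
  `zeta` to its mean, every weight to `h`, and the objective towards zero
  regardless of fit quality). The L-BFGS-B refinement is bounded to a
  trust region around the SVD initialization (axis slopes ±0.18,
  in-plane centre ±20 mm) — without bounds a weighted orthogonal-distance
  line objective can escape to degenerate far-away configurations on
  blob-shaped clusters. The axis is parameterized as `(a, b, 1)/||.||`,
  which is smooth around the near-vertical solutions where spherical
  angles are singular, and the centre's axial position is fixed at the
  electrode plane to remove the gauge freedom of a line.
* **Safety limit branches.** The rms current limit is 100 uA below 1 kHz,
  `100 uA * f/1 kHz` between 1 kHz and 100 kHz, 10 mA above 100 kHz; at
  the two boundary frequencies the lower adjacent branch applies (the
  printed branches are ambiguous there).

## What the synthetic phantoms do and do not show

The generator emulates the *study conditions*: tissue compartments with
the tabulated 100 kHz conductivities, a single-plane 16-electrode belt,
noiseless measurements, and two shape families (verification cylinder,
deformed realistic cross-section). It does not emulate electrode movement
or contact failure, anisotropic muscle conductivity, frequency dispersion,
measurement noise (available as an option but off by default, as in the
study conditions), or patient-specific anatomy. Passing tests therefore
show the *method* is implemented coherently and behaves as reported under
idealized conditions; they do not show clinical viability.

The default problem sizes are a simulation mesh of about 33k tetrahedra
(11 mm) and an inverse mesh of about 27k (13 mm) — deliberately coarser
than the ~230k-element meshes the binning constants were calibrated to
(the `N0/N` factor compensates the sample count). At this scale the
five-run study completes in minutes on a single core.

## Known limitations

* The one-step linearized reconstruction is formally outside its validity
  region: the bone/muscle contrast is ~95-99 %, so `J ds` explains only
  part of `dV`. The segmentation is designed around this (adaptive bins,
  discard rules), but residual artifacts remain, and with the homogeneous
  reference (configuration 1) on the strongly deformed realistic shape the
  skin/fat shell response can fragment the bone's signature — runs with
  the shells included in the reference (configurations 2/3) are markedly
  more robust in this implementation.
* The truncated reconstruction smears the bone dip, so the surviving
  bone cluster carries a halo of moderately negative elements well beyond
  the anatomical bone (its bone-overlap fraction is typically 0.2–0.45
  rather than the ideal near-1); for the concentric verification geometry
  this halo is symmetric and does not harm the centre estimate.
* Cluster shape, not conductivity amplitude, drives the axis fit; on
  nearly isotropic clusters the fitted direction is weakly determined and
  the bounded refinement essentially returns the initialization.
* Only the femur is modelled; distinguishing tibia from fibula in the
  lower leg is out of scope.
* Complex admittance (permittivity) and multi-plane belts are not
  modelled.
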