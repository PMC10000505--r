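---
title: "Designing UWB helmet hyperthermia applicators with helmetplan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing UWB helmet hyperthermia applicators with helmetplan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(helmetplan)
```

## The design problem

Deep microwave hyperthermia heats a tumor to 40-44 °C while keeping healthy
tissue at or below 42 °C. For brain targets, a semi-spherical "helmet" of
ultra-wide-band antennas (250-500 MHz) arranged freely around the scalp can
outperform the conventional rings of equally spaced elements, but it turns
antenna placement into a global optimization over `2 * nc` surface
coordinates. The bottleneck is the cost function: scoring one candidate
arrangement requires the E-field of every element, and a full-wave
simulation per element per candidate is far too slow for thousands of
candidates.

`helmetplan` implements the fast design chain that removes this bottleneck:

1. **Bolus geometry.** An axis-aligned ellipsoid is fitted by linear least
   squares to a scalp point cloud offset outward by the bolus stand-off
   (~5 cm). A caudal trim plane (perpendicular to z) leaves an opening for
   breathing. Every antenna pose on this surface gets a local right-handed
   frame (U, V, W): W is the inward surface normal, U the cranially oriented
   tangent in the plane of W and the body axis (the polarization axis), and
   V completes the triple. The pose origin is retracted inward until the
   antenna back plate's corners stay inside the water.
2. **Surface grid.** `n` grid nodes are spread over the available (trimmed)
   surface by minimizing the sum of inverse squared chordal distances over
   all pairs — the repulsion of like charges — with a multi-start
   local minimization (L-BFGS-B on the (theta, phi) coordinates with an
   analytic gradient, 8 seeded starts by default). Nodes are triangulated by
   mapping them to the unit sphere and taking the 3-D convex hull, which on
   a convex surface is the spherical Delaunay triangulation; faces whose
   vertices all hug the trim ring close over the caudal opening and are
   discarded. "Nearby pairs" are defined as triangulation edges, and the
   recorded max/mean edge lengths are the grid's sampling statistics.
3. **Field interpolation.** One field per (node, frequency) is precomputed.
   A query pose is answered by locating its triangular patch, dividing each
   corner field by the local intrinsic impedance (an H-field surrogate that
   is far less anatomy-dependent, since tissue is non-magnetic), rigidly
   transforming each surrogate from the corner frame to the query frame
   (positions and vector components), multiplying the impedance back, and
   blending with barycentric area-ratio weights.
4. **Coupling.** A passive neighbor re-radiates a copy of its individual
   field scaled by `k = c * e`, where `e` is the impinging field projected
   on the passive element's polarization axis at its phase center
   (14 mm inward of the ground plate) and `c` is a per-frequency complex
   constant fitted by least squares over seeded random pair experiments
   (30 by default). An array is corrected by the matrix power `M^(K-1)`
   with unit diagonal and `c e_ij` off-diagonal (K = 3 propagations by
   default; K = 1 is the uncorrected identity).
5. **Planning.** The multi-frequency SAR is the incoherent sum over
   frequencies of coherent channel superpositions,
   `SAR = sum_f sigma_f/(2 rho) |sum_c chi_fc E_fc|^2`, smoothed by 5 g
   mass averaging and scored by the hot-to-cold spot quotient
   `HCQ = mean SAR of the hottest q-fraction of healthy tissue /
   mean SAR of the coldest p-fraction of the target`, with
   `q = p |T| / |R|` and the first 20 mm of tissue under the bolus excluded
   from the healthy mask (the water cools that rind). Steering parameters
   are optimized by an iterative time-reversal-style scheme (below).
6. **Arrangement optimization.** Constrained random search — uniform-area
   draws rejected against pairwise clearance (Eq.-style projected-disc
   constraint) and eye-exclusion discs, `round(n_patches / nc)` candidates —
   followed by local refinement of the candidates in ascending cost order,
   stopping when a refinement comes out worse than the best refined value.
7. **Bioheat.** The chosen plan is scaled by a factor kappa so that the
   steady-state Pennes solution peaks at 42 °C in healthy tissue; target
   quality is reported as T50 and T90 (the temperatures exceeded by 50%
   and 90% of the target volume).

## The analytic field oracle

A full-wave solver is out of scope; the package ships a ray-based oracle
that stands in for it:

```
E(x) = A * D(psi) * P(x) * exp(-j * integral of k~(s) ds) / max(s, s0)
```

with `s` the distance from the phase center, `D = cos^2(psi/2)` a smooth
forward-directivity taper about W, `P` the polarization axis U transported
transversally along the ray, and `k~` the complex wavenumber accumulated
through the traversed tissues (midpoint quadrature, nearest-voxel lookup).
The amplitude normalizes accepted power using the source-medium wave
impedance, so the volume integral of `sigma |E|^2 / 2` never exceeds the
accepted power and approaches it in a closed absorbing phantom.

The oracle is smooth in the pose coordinates, polarized, dispersive, and
anatomy-dependent — the properties the interpolation, coupling and
optimization machinery actually rely on. It does **not** model diffraction,
multiple scattering, standing waves between tissue interfaces, or antenna
feed effects. Consequently, passing tests demonstrate that the design
chain is correct and self-consistent, not that its error figures transfer
quantitatively to full-wave fields: distribution errors against real
simulations will differ in magnitude even though their qualitative behavior
(peaking mid-patch, shrinking with grid density, improving with coupling
order) is reproduced.

## Synthetic anatomy

Two generators define the study conditions:

* `build_layered_sphere_phantom()` — the coupling-calibration phantom: a
  96.9 mm sphere with 6.3 mm skin, 6.8 mm cortical bone and 10.7 mm CSF
  shells around a brain core, inside a water bolus annulus (~5 cm) and air.
  Voxels are labeled by their center (winner-takes-all, no partial-volume
  weighting), matching the down-sampling spirit of voxelized treatment
  planning.
* `build_synthetic_patient()` — an ellipsoidal layered head (default scalp
  semi-axes 75/92/94 mm, i.e. the fitted bolus minus the 5 cm stand-off)
  with the same shell thicknesses, gray/white matter compartments, two eye
  globes, muscle fill caudal to the brain stem (emulating the rest of the
  body), and a default 126 mL spherical tumor in the dorsal brain — the
  medulloblastoma volume of the study conditions. The seed only jitters the
  tumor center by up to 2 mm; everything else is deterministic.

The shipped property table (`inst/extdata/tissue_properties.yaml`) carries
IT'IS-style dielectric values at exactly the three operating frequencies
plus thermal properties; tumor thermal values are rho = 1090 kg/m^3,
cp = 3421 J/kg/K, k = 0.49 W/m/K. Dielectrics are a versioned constant
file, overridable via `load_property_table(path)`; there is no Cole-Cole
evaluation at other frequencies.

## Numerical choices and open design points

* **Impedance.** The local impedance used by the H-surrogate is the complex
  intrinsic impedance of the lossy medium, `eta0 / sqrt(eps_r - j
  sigma/(omega eps0))`. Whether the magnitude-only (lossless) form should
  be used instead is genuinely open; both are implemented
  (`lookup_properties(..., impedance = "lossless")`), the division is
  exactly undone on restoration, so round trips cannot be biased by the
  choice. Complex is the default because the surrogate then captures the
  loss-induced phase structure.
* **Resampling.** Rigid field transformation resamples with trilinear
  interpolation on the real and imaginary parts per component — smooth
  enough for the finite-difference gradients of the refinement stage at a
  fraction of the cost of spline schemes. Out-of-lattice samples become
  zero (conservative for SAR) and their fraction is reported. Identity
  transforms and whole-voxel shifts take exact paths so grid nodes
  reproduce their stored fields to machine precision.
* **Repulsion distance.** Chordal (3-D Euclidean) distances, matching the
  charged-particle analogy; the objective is non-convex, hence the
  multi-start. Whether published "nearby pair" statistics refer to
  triangulation edges or a nearest-neighbor notion is unspecified in the
  field; this package defines them as triangulation edges and records both
  (`max_edge`, `mean_edge`).
* **Percentiles.** Nearest-rank on cumulative voxel mass, with voxels mass-
  weighted in tail means; T50/T90 are volume-weighted nearest-rank
  percentiles (50th, 10th).
* **5 g kernel.** A cube grown in whole-voxel shells until the in-mask mass
  reaches 5 g (IEC-style); surface voxels therefore average one-sidedly over
  at least 5 g and at most 5 g plus one shell.
* **Exclusion layer.** Euclidean distance transform (separable squared-EDT)
  from the non-patient region, threshold 20 mm.
* **Steering optimizer.** Iterative time reversal is implemented as: from
  the incumbent steering, identify the cold-p and hot-q voxel sets on the
  mass-averaged SAR; per frequency, maximize the generalized Rayleigh
  quotient of the cold-set versus hot-set channel covariances via the
  dominant generalized eigenvector; re-allocate power across frequencies
  toward the better single-frequency quotients; accept only improvements
  and stop at a fixed point (tolerance 1e-4, 50 iterations cap). Uniform
  and 200 random steerings are evaluated as competing initializations, so
  the returned plan is never worse than any of them. The exact update rule
  of published time-reversal planners is not specified at this level;
  the implementation is validated against its competitive contract
  (never worse than random/grid competitors on test problems) rather than
  against a reference implementation.
* **kappa search.** The steady-state solution is affine in the power
  scale, so the healthy-tissue maximum is a strictly increasing
  piecewise-linear function of kappa; bisection on that function (two
  linear solves total) replaces gradient descent — same fixed point, no
  step-size tuning.
* **Refinement.** L-BFGS-B on the pose coordinates with 0.5-degree
  finite-difference steps and a quadratic penalty on clearance violations;
  the best feasible point evaluated is returned, so refinement is monotone
  by construction. Ties between equal refined costs resolve toward the
  earlier (lower unrefined cost) candidate.
* **Perfusion.** Constant per tissue (no thermoregulation), with blood
  properties rho_b c_b = 3.6e6 J/m^3/K and T_b = 37 °C. The water bolus is
  not meshed thermally; it acts through the 100 W/m^2/K, 30 °C Robin
  condition, while air faces use 8 W/m^2/K, 20 °C.

## Problem sizes

The package's test suite and examples run the chain at desk scale by
choice: 8-10 mm lattices for the sphere phantoms, 24-node banks for
interpolation tests, grid densities 55/110/221 for the convergence study,
two-channel toys for optimizer contracts, and 4 mm only where the study
conditions demand it (tumor voxelization, wavelength-per-voxel checks).
These sizes preserve every contract being tested — exactness, monotonicity,
recovery within stated tolerances — while keeping a full run in minutes on
one CPU. Deep-target placement contracts (opposed beats adjacent) are
exercised at 250 MHz: that frequency dominates deep heating in a lossy
head (it carries the largest share of treatment power in multi-frequency
plans), whereas at 500 MHz the attenuation through 5+ cm of tissue erodes
the advantage of opposing illumination.

## Known limitations

* The oracle's straight-ray propagation underestimates interference
  structure; hot-spot localization on real anatomy requires full-wave
  fields imported through the field-set container.
* The absorbed-versus-accepted power identity of the oracle carries a
  near-source discretization deficit that shrinks with voxel size (about
  10-20% at 4-8 mm); it is a property of the lattice quadrature, not of
  the normalization.
* Antenna rotation about W (polarization angle) is not a design variable;
  eye exclusion uses a radially projected disc, a conservative
  simplification of the true shadow.
* Tissue properties are tabulated at exactly 250/375/500 MHz; no
  interpolation in frequency is offered anywhere in the chain.
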