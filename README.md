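# helmetplan

SAR-based design of ultra-wide-band (250–500 MHz) **helmet applicators** for
deep microwave hyperthermia of brain tumors.

Clinical hyperthermia heats a tumor to 40–44 °C while healthy tissue must stay
at or below 42 °C. For intracranial targets, a semi-spherical array of
self-grounded bow-tie antennas in a water bolus around the head can deliver
the dose more selectively than conventional antenna rings — if every
element's position on the bolus surface is treated as a design variable. That
turns applicator design into a global optimization whose cost function
requires the E-field of every antenna at every candidate location.

`helmetplan` is aimed at researchers in computational hyperthermia treatment
planning. It implements the fast design chain that makes the search
tractable:

* **Field interpolation.** Single-antenna fields are precomputed on a grid of
  `n_p` surface locations spread by electrostatic repulsion (minimizing
  Σ 1/d² over all pairs) and triangulated. The field at an arbitrary pose is
  obtained by dividing each patch-corner field by the local intrinsic
  impedance η (an H-field surrogate, nearly anatomy-independent since tissue
  is non-magnetic), rigidly transforming it into the query frame, restoring
  E = η·H, and blending with barycentric area-ratio weights
  `E_a = ω₁Ê₁ + ω₂Ê₂ + ω₃Ê₃`.
* **Mutual coupling.** A passive element re-radiates `k·E_P` with
  `k = c·⟨U_P, E_A(O'_P)⟩`; the complex constant `c` is fitted per frequency
  by least squares over seeded pair experiments, and an `n`-element array is
  corrected by the truncated reflection series `(I + C + … + C^{K−1})`
  (default K = 3 propagations).
* **Treatment planning.** Multi-frequency SAR
  `SAR = Σ_f σ_f/(2ρ) |Σ_c χ_{f,c} E_{f,c}|²` is smoothed by 5 g mass
  averaging and scored by the hot-to-cold spot quotient
  `HCQ_p = S̄AR_R^q / S̄AR_T^p` (mean SAR of the hottest q-fraction of healthy
  tissue over the coldest p-fraction of the target, `q = p·|T|/|R|`, with the
  20 mm surface rind under the bolus excluded). Steering parameters χ are
  optimized by an iterative time-reversal scheme built on generalized
  eigenvectors of cold-spot/hot-spot channel covariances.
* **Arrangement optimization.** Constrained random search
  (`round(n_patches/n_c)` candidates, pairwise clearance + eye-exclusion
  constraints) followed by sorted local refinement with early stopping.
* **Bioheat evaluation.** Steady-state Pennes solve
  `∇·(k∇T) − ρ_b c_b ω (T − T_b) + κ·PLD = 0` with convective boundaries
  (8 W/m²/K air at 20 °C, 100 W/m²/K water at 30 °C); κ is scaled so the
  healthy-tissue maximum hits 42 °C, and target quality is reported as
  T50/T90.

A ray-based analytic **field oracle** (polarized, attenuated, dispersive
outgoing waves with known ground truth) stands in for a full-wave solver, so
the whole chain runs on synthetic voxel phantoms: a layered sphere
(96.9 mm outer radius; 6.3/6.8/10.7 mm skin/bone/CSF shells) for coupling
calibration, and an ellipsoidal layered head with a 126 mL dorsal tumor as a
synthetic patient. External solver fields can be supplied through the
field-set container instead.

## Worked example

Two opposed antennas at 250 MHz heating a centered deep tumor in the layered
sphere phantom:

```r
library(helmetplan)

# phantom: study shells, 20 mm deep tumor, 8 mm lattice
spec  <- phantom_spec(bolus_thickness = 30,
                      tumor = list(center = c(0, 0, 0), radius = 20))
model <- build_layered_sphere_phantom(spec, spacing = 8)
#> Warning: shells thinner than one voxel: skin, bone
masks <- build_evaluation_masks(model, p = 50)        # q = p|T|/|R|
masks
#> Masks: target 41.5 mL, remaining 1957.9 mL, p = 50%, q = 1.06%

# two opposed antennas on the mid-bolus sphere
surf <- ellipsoid(rep(96.9 + 15, 3))
poses <- list(antenna_frame(surf, pi/2, 0,  retract = FALSE),
              antenna_frame(surf, pi/2, pi, retract = FALSE))
f <- 250e6
fields <- list(lapply(poses, oracle_antenna_field, model = model, f = f))

# steering optimization and thermal evaluation
plan <- optimize_steering(fields, model, masks, f, seed = 1)
summary(plan)
#> Treatment plan: HCQ = 108.1230 over 2 channels x 1 frequencies
#> Power fractions [%]:
#>     250MHz antenna total
#> ch1     50            50
#> ch2     50            50
#> Frequency totals: 100

thermal <- scale_power_to_limit(model, fields, plan$chi, f, limit = 42)
thermal
#> Thermal result: kappa = 3.93, max healthy T = 42.00 degC, T50 = 37.01, T90 = 37.01
```

The mirror-symmetric optimum splits power evenly between the two channels;
the HCQ ≈ 108 says the hottest healthy-tissue percentile still receives two
orders of magnitude more (mass-averaged) SAR than the coldest half of this
deep 42 mL target — two antennas at one frequency cannot focus more sharply
through 50+ mm of lossy tissue, which is exactly why helmet arrays with more
elements and multi-frequency steering are worth optimizing. After scaling to
the 42 °C healthy-tissue limit the deep target median only reaches T50 ≈ 37.0 °C.

Full-array design (random search + refinement) runs through
`design_applicator()`; a thin command-line front end with `phantom`, `grid`,
`plan`, `design` and `thermal` subcommands is installed at
`inst/cli/helmetplan`.

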