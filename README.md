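# hingefit

Registration and validation of the mandibular axis of rotation (hinge
axis) from dual-bite intraoral scans.

## The problem

Virtual articulators need an axis of rotation for the lower jaw. Motion
tracking hardware measures it directly but is expensive; a
radiation-free alternative is to compute the axis from two intraoral
scan poses of the same arches — one closed bite and one opened on a
~2 mm bite block — exploiting the fact that a modern scanner exports the
*identical* mesh in both poses, so every vertex is an anatomical
landmark with known correspondence.

The catch is that the displacement between the two poses is never a pure
rotation: bite re-seating, scanner alignment error and physiological
translation all contaminate it. A rotation-only fit then returns an
*instantaneous centre of rotation* (ICR) that can sit tens of
millimetres from the anatomical hinge while still fitting the scans
almost perfectly. `hingefit` implements the axis fit together with the
machinery to quantify exactly this behaviour:

- **Axis fit** — two-stage corresponded least squares: a closed-form
  rigid superposition (Kabsch) whose screw decomposition (Chasles'
  theorem, pitch discarded) seeds a rotation-only Levenberg–Marquardt
  refinement over five parameters (axis direction 2, in-plane position
  2, angle 1). No nearest-neighbour search; correspondence is by vertex
  index.
- **Canonical axes** — every axis is re-parameterized as a 200 mm
  segment centred on the projection of the reference mesh centroid, so
  replicate axes are comparable. `d_axis` is the mean of the start- and
  end-point distances of two such segments.
- **Error propagation** — EcD (axis displacement in mm per mm of
  registration error; for in-plane translational error it equals
  `1/(2 sin(θ/2))`, ≈ 37.4 at θ = 1.53°) and AEcFE (axis discrepancy per
  mm of final mesh-position error after an articulator rotation;
  `1/(2 sin(θ/2))` = 57.3 / 28.6 / 19.1 at 1° / 2° / 3° for parallel
  offsets).
- **Simulation setups** — reproducibility trials within an axis group,
  cross-validation of fitted axes against reference (motion-tracking
  style) axes, the shared-fixed-mesh EcD experiment, the reversed
  control (rotating the closed scan about reference axes to best overlap
  with the open scan), and a direction-resolved sensitivity scan of axis
  perturbations, all reported with rms/max deviation metrics and 0.1 mm
  clinical-threshold tallies.
- **Synthetic data** — a seeded generator of dental-arch meshes and full
  dual-bite scan sessions (triplicate closed scans CA1–3/CB1–3, open
  scans OA1–3/OB1–3, replicate reference axes with calibrated scatter,
  rigid alignment noise calibrated to an exact rms), so the entire
  pipeline runs and is tested without any external data.

## Worked example

```r
library(hingefit)

session <- make_session(arch_params(seed = 11), scan_scenario(seed = 11))
session
#> scan_session: 12 scans (CA1/CB1/OA1/OB1), 5 reference axes, opening 1.348 deg, seed 11

fit <- fit_rotation_axis(session$scans$OA1, session$scans$CA1)
fit
#> axis fit CA1:OA1: angle 1.4681 deg, residual rms 0.096254 mm (max 0.188739), 11 iterations

truth <- canonicalize_axis(session$truth_axis, session$scans$CA1)
compare_axes(fit$axis, truth)
#> axis_comparison: d_axis 16.8906 mm (start 19.6519, end 14.1292), angle 8.0037 deg

screen <- flag_outlier_axes(session$modjaw_axes, session$base_mesh)
trials <- run_setup2(list(canonicalize_axis(fit$axis, session$base_mesh)),
                     screen$kept, session$base_mesh)
s <- attr(trials, "summary")
#> Setup-2: 30 trials; mean max_error 0.250 mm; mean d_axis 17.00 mm;
#> 0.0% of trials < 0.1 mm
```

Read the numbers together, not separately: with realistic open-bite
alignment noise (0.145 mm rms) the fitted ICR lands ~17 mm from the true
hinge, yet the residual against the scans is below 0.1 mm — the noise,
not the fit, limits the method. And when that displaced axis is actually
used for 1–3° articulator rotations, the occlusal-level error is only
~0.25 mm, because the optimizer sheds error along directions the
articulation barely feels (large AEcFE). The sensitivity scan
(`error_direction_scan()`) makes those directions explicit, and the
variance of replicate fitted axes concentrates along the least-sensitive
one.

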