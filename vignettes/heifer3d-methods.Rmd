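---
title: "Morphometrics of growing heifers from 3D body scans: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometrics of growing heifers from 3D body scans: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heifer3d)
```

## The problem

Monitoring the growth of replacement dairy heifers requires repeated body
weight (BW) and conformation measurements, which are labour-intensive and
risky to collect by handling animals. Whole-body 3D scanning offers the
same information without contact: a portal of cameras produces a point
cloud of the standing animal, surface reconstruction turns it into a
watertight triangulated mesh, and morphological traits, body surface area
(BSA) and volume are measured on the mesh. BW is then predicted from
those traits, most effectively from volume alone.

`heifer3d` implements the full analysis chain in R: a parametric
synthetic-heifer generator with closed-form ground truth (the stand-in
for the scanning device), point-cloud surface reconstruction, mesh
morphometrics, scan-quality scoring, BW prediction and refitting, and
longitudinal growth analysis.

## The synthetic animal

No per-animal raw data were deposited by the study this package follows,
so every stage is validated against a parametric quadruped whose traits
are known in closed form. The body is a union of analytic solids:

* a torso: superellipsoid along the body axis with profile exponent
  $n$ (`torso_taper`; 2 = ellipsoid, larger = boxier) and superelliptical
  cross-sections with exponent $m$ (`section_exponent`);
* four vertical capsule legs with hemispherical feet touching the ground;
* a capsule neck and an ellipsoidal head.

Cross-sections of the torso at a fraction $u$ of its half-length are
superellipses scaled by $s(u) = (1-|u|^n)^{1/n}$, which makes every
landmark trait closed-form: chest depth $2c\,s$, widths $2b\,s$, heart
girth the superellipse perimeter (computed by dense quadrature), withers
height the torso top over an axial window. Volume combines closed-form
primitive volumes with voxel-counted pairwise overlaps (the voxel pitch
is proportional to torso length, so ground truth scales *exactly* under
similarity transforms — a property the test suite asserts at 1e-9).
Surface area integrates each primitive's parametric surface and discards
patches hidden inside another primitive.

**Presets.** `shape_preset("month02")` … `"month20"` are calibrated so
that ground-truth withers height, chest depth, heart girth, buttock width
and volume reproduce the published stage means of the pilot population
(five Holstein heifers scanned monthly from 5 weeks to 20 months). The
calibration solves, in order: the taper exponent from the buttock width,
the torso section semi-axes from chest depth and heart girth, the torso
axis height from withers height, and body length from volume. Where the
buttock-width target cannot be reached with the default boxy section
($m = 2.8$), $m$ is relaxed towards elliptical in 0.1 steps; boxy
sections are preferred because, with girth and depth pinned, they give
the higher surface-to-volume ratio characteristic of real animals.

A deliberate limitation: with heart girth, chest depth and volume pinned
to the published means, a smooth convex body cannot reach the full
image-derived BSA (the study's own allometric cross-check shows the same
gap — image BSA at 84.5 kg is 2.73 m² where the classical formula gives
1.76 m²). Real surfaces carry ears, tail, dewlap, folds and hair that a
smooth union of primitives does not. The presets therefore sit in the
lower part of the published BSA envelope (4.70 m² at one year against
5.21 ± 0.32 m² published, inside ±2 sd). Passing round-trip tests shows
the *measurement* chain is accurate on smooth bodies; it does not show
that a smooth model captures all surface detail of a real heifer.

**Growth.** BW follows a monomolecular (Brody) curve
$BW(t) = A - (A - BW_0)e^{-kt}$ with defaults $BW_0 = 40$ kg, $A = 680$
kg, $k = 0.00191\,\mathrm{d^{-1}}$: the published stage means are nearly
linear over 2–20 months, so the asymptote is fixed at a typical Holstein
mature weight and only the rate is fitted. "Asymptotic" trait curves are
obtained through allometric links $\mathrm{trait} = a\,BW^b$ fitted on
the stage means (log–log). Volume is $BW/\rho$ with a constant body
density $\rho = 900\ \mathrm{kg\,m^{-3}}$, chosen so that volume-only
linear BW equations (slopes near 900 kg m⁻³) are recoverable by
refitting. `simulate_herd()` draws per-animal log-normal deviations of
$A$ (cv 8%) and $k$ (cv 5%) — magnitudes that reproduce a between-animal
BW spread at one year comparable to the published ±47 kg — and adds
per-visit Gaussian measurement noise (defaults: 1.2 cm on heart girth,
0.5–0.8 cm on the other linear traits, 0.06 m² on BSA, 0.008 m³ on
volume, 4 kg on the scale). Per-animal seeds derive from
`seed + animal index`, so everything is reproducible.

## Meshing and reconstruction

Surfaces are extracted by **marching tetrahedra** on a uniform grid
(each cube split into six tetrahedra around its main diagonal). Unlike
marching cubes this has no ambiguous cases, so the output is watertight
and consistently oriented by construction; global orientation is fixed
by requiring positive signed volume. `resolution` maps to grid pitch as
$h = 2\pi r_{\min}/\mathrm{resolution}$ with $r_{\min}$ the thinnest
primitive radius, i.e. resolution counts angular subdivisions of the
smallest limb. Measured volume converges as $O(h^2)$: a sphere preset is
within 1% of closed form at resolution 64 and 0.1% at 256.

`reconstruct_surface()` implements implicit-function reconstruction from
an oriented point cloud: the signed field at a grid node is the
distance-weighted mean of tangent-plane offsets
$n_i\cdot(x - p_i)$ over the $k = 10$ nearest points, evaluated exactly
in a narrow band around the cloud; outside the band only the sign is
needed and is flood-filled. The default grid pitch is 2.5 times the
median point spacing — coarse enough to average scanner noise (2 mm in
the simulated device), fine enough that volume error stays well inside
the 5% round-trip contract. Screened-Poisson internals are deliberately
*not* re-implemented: the analysis depends only on the watertight-mesh
contract, and the stage is pluggable. `estimate_normals()` is classical
PCA normal estimation with orientation propagated over a minimum
spanning tree of the neighbourhood graph and a global flip so normals
point away from the centroid.

`make_watertight()` closes holes by fan-filling boundary loops; it
refuses inputs with more than 10% boundary edges or loops longer than
30% of all edges, where fan filling would fabricate a substantial share
of the surface.

## Morphometrics

The body frame is fitted by PCA of the ground-projected vertices; up is
+z (animals stand on the device floor); the muzzle end is the end with
the smaller lateral spread. Landmark planes are *fractions of body
length* from an anatomy table (heart girth 0.30, hip 0.78, buttock 0.92,
withers window ±0.05) rather than learned anatomical detection — the
fractions are transparent, configurable and testable. Heart girth is the
perimeter of the **convex hull** of the cross-section, emulating a taut
tape over concavities; heights are referenced to the lowest mesh point
(the floor). Volume uses the divergence theorem and refuses
non-watertight input rather than returning a silent partial volume;
`measure_all()` records individually failed traits as `NA`, because a
partially digitised animal can still yield valid linear traits.

A published-table ambiguity is handled explicitly: the study's table
column labelled hip width numerically matches its withers-height values
in the text. The package treats hip width (`hw`) and withers height
(`wh`) as distinct traits, calibrates the generator's `wh` to that
column, and leaves `hw` unconstrained by it.

## Quality scoring

The study scored each scan 1–4 visually. The package operationalises the
scale: the leg zone (ground to torso underline, capped at 0.55 × withers
height) is sliced at 10 heights; a slice with fewer than 4 separate
sections is webbed, the webbed fraction is the skirt severity, and the
flag threshold is 0.2. Missing regions are judged against quadruped
anatomy (a head should overhang the forelegs by ≥ 0.30 of body length;
legs should exist below the torso underline). Score 4 = watertight, no
skirt, nothing missing; 3 = skirt severity ≤ 0.4 only; 2 = exactly one
major defect (non-watertight, missing region, or severity > 0.4); 1 =
two or more. Records scoring ≤ 2 are excluded from BSA/volume analyses
but keep their valid linear traits; both BSA and volume gate at score ≥
3 (the study does not say whether its score 3 allowed volume — one gate
for both is the simpler, conservative reading). `inject_skirt()`
reproduces the defect by unioning membrane boxes between each leg pair
into a signed-distance resampling of the mesh, so corrupted meshes stay
watertight while volume and area strictly increase.

## Weight models and refitting

`builtin_models()` carries the eight published equations with
coefficients stored as decimal strings (serialization round-trips them
bit-exactly). Units are SI throughout (volume m³, BSA m², traits m, BW
kg). Two published equations (the full trait equation and the
volume+hip-width refit) do not reproduce their printed predictions when
evaluated in metres at the published stage means — the original units
are not stated — so the package documents the discrepancy instead of
silently rescaling; predictions from those equations should be treated
with that caveat.

`fit_weight_model()` is OLS with two documented conventions: forced
through the origin, R² is the uncentered form (about zero), which is
what base R reports for intercept-free fits; and significance pruning is
backward elimination on t-tests at α = 0.05 by default. Backward
elimination re-tests every surviving predictor at each step, so its
per-predictor type-I rate exceeds the nominal α (about 10% here,
measured by simulation); with four spurious predictors, the chance that
*all* are discarded in one run is roughly 60–70%, not $0.95^4$. This is
a property of the procedure itself and is discussed rather than hidden:
single-run pruning results should be read as indicative, not as a
specificity guarantee.

## Longitudinal analysis

BW is linearly interpolated in age between weighing dates (records are
14–28 days apart; anything smoother is unidentifiable at that spacing),
never extrapolated. Stage summaries use the published stage ages ± 15
days and sample standard deviations. The surface-to-volume ratio
BSA/volume (m⁻¹) is fitted against BW as a power law
$a\,BW^{-b}$ on the log–log scale — geometric similarity predicts
exactly $b = 1/3$, and the package recovers that to 1e-6 on noiseless
isometric records; the decreasing-exponential form
$a\,e^{-b\,BW}$ is available behind `model = "exponential"`.

## Numerical choices and problem sizes

* Marching-tets zero crossings are clamped to $[10^{-6}, 1-10^{-6}]$
  along grid edges, so exactly-zero field values cannot create
  degenerate faces; grid padding uses a non-integral multiple of the
  pitch to keep nodes off symmetric surfaces.
* Cross-section polygons are chained by edge identity (not coordinate
  rounding); polygons under 1e-6 m² are discarded as tangency noise.
* Ground-truth voxel overlap pitch is torso length / 400 (≈ 2 mm at one
  year); BSA quadrature uses 600 × 600 parametric patches for the torso.
* The test suite exercises presets at resolution 128 (the refinement
  check compares 128 vs 256 on the one-year preset) and reconstruction
  at 100k points with 2 mm noise; the pipeline default is 2 animals x 3
  visits at resolution 48. These sizes keep a full run in minutes on one
  core while leaving discretisation error an order of magnitude below
  every tolerance asserted.

## Worked example

```{r example, eval = FALSE}
bm <- build_heifer_mesh(shape_preset("month12"), resolution = 96)
rec <- measure_all(bm$mesh, "demo", age = 369)
rec$hg * 100   # heart girth, cm  (study: 188.1 +/- 3.7 at one year)
rec$volume     # m^3              (study: 0.43 +/- 0.05)
predict_bw(builtin_models()$eq8, rec)  # volume-only BW estimate, kg

herd <- simulate_herd(growth_params(), 5, seq(35, 620, by = 28), seed = 1)
sv <- surface_to_volume_curve(herd$traits, herd$weights)
coef(sv)       # decay exponent b near 1/3
```

## Known limitations

* The generator is a smooth rigid solid: no pose variation, coat, ears
  or tail; BSA of real scans will exceed the synthetic envelope's lower
  range (see above), and defects beyond skirts and missing regions
  (e.g. motion ghosting) are not modelled.
* Landmark stations are fixed fractions of body length; on animals with
  atypical proportions a fractional station is not an anatomical
  landmark.
* The published per-animal data are not available, so agreement is
  demonstrated against printed stage means and envelopes, not against
  raw observations.
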