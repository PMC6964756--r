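---
title: "Methods: independent point-dose verification for Gamma Knife plans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: independent point-dose verification for Gamma Knife plans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Why a secondary dose calculation

Gamma Knife radiosurgery delivers ablative single-fraction doses through 192
Co-60 beams focused on one point, so an independent re-computation of the
planned point dose is required before every treatment; clinical policy
(following AAPM TG-40 practice) demands agreement with the treatment planning
system within 5%. Verification engines historically struggle in two regimes:
shallow calculation points near the skull surface, where the fidelity of the
rendered skull dominates, and nonstandard *gamma angles* (head tilts of 70 or
110 degrees instead of the standard 90), where every beam path through the
head changes. `icondose` implements a verification engine designed for
exactly these regimes: the skull is rendered by image thresholding (or, for
compatibility, from 24 scalar radius measurements), and nonstandard gamma
angles are handled by applying the rotation matrix to every beamlet
individually rather than by any approximate correction.

## Unit geometry and the gamma rotation

The unit is modelled as 8 azimuthal sectors of 24 sources (192 total) grouped
in rings at fixed polar angles from the superior axis, every source focused
on a single focus point. Coordinates are Leksell-style: right-handed
millimetres, focus at (100, 100, 100), x patient left–right, y
posterior–anterior, z inferior–superior. The vendor's exact source map is
proprietary, so the shipped default (`extdata/icon_like_default.json`) is an
honest approximation preserving the published topology: five rings at
36–72 degrees polar with focal distances 370–435 mm and 4–5 sources per
sector per ring. Every number is a configuration entry, not a constant, so a
site that knows better coordinates can supply them without touching code.

A *beamlet* is the ray from one source through the shot isocenter. For a
plan at gamma angle $\gamma$ the canonical source positions are rotated by
$(\gamma - 90)^\circ$ about the x-axis through the focus (gamma 110 is $+20^\circ$
by our stated sign convention, gamma 70 is $-20^\circ$; the convention is
recorded in the geometry configuration so the handedness can be flipped
without a code change), then translated so the focus coincides with the shot
isocenter. The package rotates beamlets rather than counter-rotating the
skull — the two are rigidly equivalent, and the test suite verifies that
equivalence numerically rather than assuming it ("gamma equivalence"):
computing at gamma $g$ against a skull $S$ equals computing at gamma 90
against $S$ rotated by $-(g-90)^\circ$ at correspondingly rotated points, to
machine precision on closed-form skulls and to a few times $10^{-4}$
relative on 1 mm voxel masks.

## Skull rendering

Three interchangeable realizations answer the same two queries —
`skull_inside()` and `first_intersection()` (first outside-to-inside
crossing along a ray):

* **Threshold mask** (`threshold_skull()`): a CT voxel is inside the skull
  when its value is at least the threshold (default $-400$, midway between
  air and soft tissue on the HU scale); MR images use a configurable
  two-sided band because MR intensity is not calibrated. The raw binary
  volume is closed with a one-voxel 6-neighbourhood structuring element and
  reduced to its largest connected component before any ray query — speckle
  outside the head, or a hole inside it, would otherwise corrupt entry
  points. Rays are traced by parametric (Amanatides-style) voxel stepping
  over half-open voxel intervals, with corner ties resolved toward the axis
  with the smallest parametric step so entry points are orientation
  independent. The face hit is then refined to sub-voxel precision by
  bisecting the 0.5 level set of the trilinearly interpolated occupancy;
  against closed-form sphere and ellipsoid surfaces the resulting entry
  error stays below half a voxel diagonal at 1 mm spacing.
* **Scalar measurements** (`skull_from_measurements()`): 24 radii from a
  dome centre on a 3-ring (30/55/80 degrees from vertex) by 8-azimuth grid,
  the instrument-style description some systems use. The radius function
  interpolates the 24 nodes exactly and bilinearly in angle (linear in
  polar angle between rings, linear and periodic in azimuth; above the first
  ring it tapers to the ring-1 mean, below the last ring it is held
  constant), and the dome is closed by a horizontal base plane at the frame
  inferior limit. Whether clinical systems interpolate these measurements
  with splines or harmonics is unpublished; bilinear-in-angle is the least
  committal interpolant that is exact at the nodes and bounded by them, and
  the grid layout is configuration-exposed. Ray queries march along the ray
  at 1 mm and bisect the bracketing interval; crossings thinner than the
  marching step can in principle be skipped, which is the stated
  approximation for near-tangential rays.
* **Analytic surface** (`gk_skull_analytic()`): an exact sphere/ellipsoid
  solved from the line–quadric quadratic. This realization exists for
  oracle-grade geometry (synthetic phantoms carry one as ground truth) and
  is labelled synthetic; it is not a clinical input path.

## Radiological depth and the dose model

For a calculation point $P$ and beamlet $b$, the depth $d_b$ is the path
length from the first skull crossing of the source-to-$P$ ray to $P$; the
interior is homogeneous water — internal cavities and re-entrant crossings
are deliberately ignored, matching the TMR-style formalism the engine
implements. Beamlets whose ray does not place $P$ inside the skull
contribute zero dose and are counted rather than raised as errors, since
shallow targets can geometrically miss inferior sources. The per-beamlet
dose rate is

$$\dot D_b \;=\; \frac{\dot D_{cal}}{192}\; OF_c\;
  e^{-\mu\,(d_b - d_{ref})}\;\left(\frac{f}{r}\right)^{2} P_c(\rho),$$

with $\dot D_{cal}$ the user's calibration dose rate (Gy/min, 16 mm
collimator, all sectors open, reference depth), $OF_c$ the collimator output
factor, $f$ the ring focal distance, $r$ the source-to-point distance, and
$P_c$ the off-axis profile
$P_c(\rho) = \tfrac12\!\left[\operatorname{erf}\!\frac{R_c-\rho}{s_c} +
\operatorname{erf}\!\frac{R_c+\rho}{s_c}\right] / \operatorname{erf}\!\frac{R_c}{s_c}$,
normalized to 1 on axis, where $\rho$ is the perpendicular distance of $P$
from the beamlet axis scaled to the focal plane by $f/r$. Defaults:
$\mu = 0.0063\,\mathrm{mm^{-1}}$ (Co-60 effective in water),
$d_{ref} = 80$ mm (centre of the standard 160 mm calibration sphere),
$OF = \{16{:}\,1.000,\ 8{:}\,0.900,\ 4{:}\,0.814\}$ (vendor-nominal,
overridable), $R_c = \{2, 4, 8\}$ mm and $s_c = \{0.6, 0.8, 1.1\}$ mm for
the 4/8/16 mm collimators. The error-function penumbra is the smoothest
two-parameter profile that reproduces realistic tails while staying exactly
normalized; all of it is a `gk_dose_params()` entry. Output factors are
normalized per unit total (the division by 192); a per-sector normalization
would only rescale $\dot D_{cal}$ for fully open plans but is left as a
parameter decision, not hard-coded physics. Co-60 decay correction
(half-life 5.2711 y) is available and off by default because paired
primary/secondary checks are same-day comparisons.

Dose is always evaluated directly at the query point — there is no
intermediate 3-D dose grid and therefore no grid-to-point interpolation,
a suspected error source in engines that compute a dose matrix first.
Dose is exactly linear in shot duration and additive over shots, and the
test suite pins the whole chain to an independently hand-rolled summation
at $10^{-12}$ relative.

### The dose maximum and z-profile asymmetry

All sources sit in the superior hemisphere. For a point displaced superior
of the isocenter, every source is slightly closer ($r$ falls) and every ray
is slightly shallower ($d_b$ falls), so both the inverse-square and the
attenuation factor rise together: the dose field of a centred shot is *not*
symmetric in z (the acceptance script measures the $+z/-z$ profile asymmetry
of a centred 16 mm shot at several percent of the central dose) and its
maximum sits a few millimetres superior of the isocenter. This is a direct
consequence of a one-sided source array and is shared by the clinical
geometry; x- and y-profiles, by contrast, are symmetric to machine precision
because the sector layout has exact reflection symmetry in those axes.
`find_max_dose_point()` therefore never assumes the maximum is at an
isocenter: it runs a coarse grid search over the padded bounding box of the
shot isocenters followed by local pattern refinement to 0.1 mm, and its
tests compare against a dense-grid oracle. `scale_plan_to_max_dose()`
exploits duration linearity, so scaling to a 4 Gy maximum is an exact fixed
point.

## Agreement statistics

The evaluation stage mirrors a clinical audit of paired
secondary-vs-reference calculations. The per-target metric is the signed
percent difference $100\,(D_{sec} - D_{ref})/D_{ref}$; the reference engine
is always designated explicitly. `cohort_evaluation()` reports the
median/mean/range of the absolute differences, the count beyond the 5%
tolerance, and three nonparametric tests, implemented in-package because
their exact-p contracts under ties differ from the base-R defaults (base R's
implementations serve as cross-checks in the unit tests):

* **Wilcoxon signed-rank** between this engine's and a comparator engine's
  absolute differences — absolute rather than signed differences are
  compared, matching how verification agreement is reported clinically;
  zero differences are dropped and counted. Exact p by full $2^n$ sign
  enumeration (valid under ties) up to $n = 15$, tie-corrected normal
  approximation beyond.
* **Mann–Whitney U** between standard (90 degree) and nonstandard (70/110)
  gamma categories. Exact p by full labeling enumeration when the smaller
  group has at most 8 members *and* the labeling count is tractable
  ($\binom{n}{k} \le 2\times10^5$ — a 30-vs-770 split is far beyond literal
  enumeration); otherwise tie-corrected normal.
* **Kendall tau-b** between absolute difference and average calculation
  depth — tau-b because depths tie after rounding to 0.1 cm; p from the
  fully tie-corrected variance of the concordance score.

## Synthetic data: what it emulates, and what it does not

No patient data ships with or is required by the package; every stage is
exercised on synthetic inputs with analytic ground truth.

* `make_phantom()` voxelizes spheres/ellipsoids with exact inside/outside
  assignment at voxel centres and carries the closed-form surface as an
  oracle. The default — an 80 mm "head" of tissue intensity in air at 1 mm
  spacing — matches the scale at which the engine runs clinically.
* `make_plan()` draws reproducible shot arrangements inside a phantom; the
  centred single-16 mm-shot default is the profile-comparison scenario.
* `simulate_cohort()` emulates the *structure* of a verification cohort:
  800 targets, average depths uniform on 2.4–10.5 cm, 30 targets at
  nonstandard gamma. Engine disagreement is a random-signed half-normal
  percent error; its magnitude mean can shift linearly in depth and by a
  nonstandard-gamma offset. The shift acts on the magnitude (not the signed
  error) because the clinically observed pattern is a *negative* rank
  correlation between the absolute difference and depth — a signed-mean
  shift would make the absolute error U-shaped in depth and unrecoverable.
  Defaults were calibrated once, at design time, to the reported clinical
  regime (half-normal scale 1.0 → median absolute difference ≈ 0.7%; depth
  slope $-0.12$ %/cm → tau ≈ $-0.3$) and a nonstandard-gamma offset of
  2.5 percentage points is of the order reported for a gamma-sensitive
  engine. These are generator defaults for producing realistic-looking
  cohorts, not a claim of equivalence with any clinical dataset.

Simulated cohorts share none of the real data's imaging physics: there is no
CT noise or artifact model, no MR bias field, and the phantoms are convex
quadrics rather than skulls. Passing tests therefore demonstrate geometric
and statistical correctness of the engine, not clinical accuracy on
anatomical surfaces.

## Numerical choices and problem sizes

Mask ray queries run in compiled code; scalar-realization queries march in R
at 1 mm with 60-step bisection ($<10^{-12}$ mm bracket). The default test
and verification workloads use 2 mm phantoms for routine checks and 1 mm
phantoms (about $190^3$ voxels) where sub-voxel accuracy is asserted; the
cohort power checks run 100 replicates of 800 targets. On one CPU the full
test suite completes in well under a minute and the acceptance script in
seconds.

## Known limitations

* Homogeneous interior: no tissue heterogeneity, no cavity handling; the
  first surface crossing defines the depth.
* Infinitesimal beamlets: finite source extent and collimator mechanics are
  not modelled; the penumbra is carried entirely by $P_c$.
* Approximate default source map (topology exact, coordinates approximate).
* Near-tangential rays on the scalar realization can skip crossings thinner
  than the marching step.
* Image input is NIfTI; DICOM series must be converted upstream.
* No DVHs, no 3-D dose export, no treatment-time optimization — this is a
  point-dose verification engine, not a planning system.
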