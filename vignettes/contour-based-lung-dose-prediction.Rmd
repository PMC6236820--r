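---
title: "Contour-based lung dose prediction: model, calibration, and phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contour-based lung dose prediction: model, calibration, and phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Highly conformal proton plans for breast and chest-wall targets have falloff
isodose surfaces that closely resemble uniform geometric expansions of the
planning target volume (PTV). `margindose` turns that observation into a
contour-only predictor of lung dose-volume metrics. For a margin $m$ (mm),
let $\mathrm{PTV}+m$ denote the isotropic expansion of the PTV and

$$V(m) \;=\; \frac{|(\mathrm{PTV}+m) \cap \mathrm{IL}|}{|\mathrm{IL}|}$$

the fraction of the ipsilateral lung (IL) inside it. If the $D$ isodose
surface really is a uniform expansion at some distance $m_D$, then the
dose-volume metric $V_D$ (the lung fraction receiving at least $D$) equals
$V(m_D)$ — and $V(m_D)$ needs nothing but contours, so the prediction is
available before any plan exists.

The margin for each dose level is calibrated on planned cases by minimising
the root-mean-square prediction error, in percentage points of lung volume:

$$m_D \;=\; \arg\min_{m'} \sqrt{\big\langle\, (V(m') - V_D)^2 \,\big\rangle},$$

with $\langle\cdot\rangle$ an average over cases. The mean error
$\mathrm{ME} = \langle V(m_D) - V_D \rangle$ is tracked alongside as a
measure of systematic bias; $\mathrm{RMSE} \ge |\mathrm{ME}|$ always. All
plans are first rescaled to a common reference prescription of
50.4 Gy(RBE), so one calibrated margin serves prescriptions from 50.4 up to
the 60s of Gy(RBE): a dose level $D$ in the reference frame corresponds to
$D \cdot \mathrm{Rx}/50.4$ in a plan prescribed at $\mathrm{Rx}$.

The shipped default model (`default_margin_model()`) maps
$20\,\mathrm{Gy(RBE)} \to 11\,\mathrm{mm}$ and
$5\,\mathrm{Gy(RBE)} \to 22\,\mathrm{mm}$.

## Calibration procedure and its parameters

`calibrate_margin()` does a grid search over margins, by default
$-10$ to $+40$ mm in steps of 0.5 mm. Negative margins shrink the PTV; they
extend the same signed-distance threshold inward and matter only when a
target overlaps the organ. The search granularity is a compromise: margins
are reported at millimetre resolution clinically, and 0.5 mm steps make the
grid-search optimum insensitive to voxel-level noise. Ties are broken toward
the smallest margin, the more conservative lung-sparing prediction.

`convergence_run()` operationalises "grow the cohort until the RMSE stops
changing": after each added case it re-evaluates the RMSE and declares
convergence at the first $n \ge 10$ whose RMSE is within `tol` (default
0.25 percentage points) of each of the previous `window` (default 3) cohort
sizes. The floor of 10 matches the smallest cohort on which a margin is
first calibrated; all three knobs are arguments. The stream order is the
caller's: treatment order, random order, or anything else.

Per-case dose handling is always: rescale to the reference prescription,
resample onto the structure grid (trilinear, zero outside the dose field),
then threshold. Structure grids define the voxel-counting frame, so dose is
brought to the structures and never the reverse.

## Geometry engine and numerical conventions

Expansion is not iterated morphological dilation: `expand_mask()` thresholds
the signed Euclidean distance map of the *original* mask at $m$, so
expansions compose exactly and nest monotonically. Distances are computed
between voxel centers with anisotropic spacing honoured (CT slices are
usually thicker than in-plane pixels), via a separable lower-envelope
distance transform in C++. Conventions, chosen once and used consistently:

* signed distance is negative inside a structure; voxels at distance exactly
  $m$ are **included** in the expansion (`<=`), which makes $m = 0$ the
  bit-exact identity;
* $V_D$ counts voxels with dose `>= D` (closed on the same side), so a
  conformal dose built from PTV distances is exactly self-consistent with
  expansion overlap;
* $D_V$ is read off the empirical step DVH without interpolation (the
  $\lceil V n \rceil$-th largest organ voxel dose), making
  $D_V(V_D(\cdot))$ exactly invertible on achieved steps; linear
  interpolation is available as an option;
* masks are defined by voxel-center membership (center-in-polygon with the
  even-odd rule when rasterising contours), 0-based indices, patient-space
  millimetres.

`v_of_m_curve()` evaluates the whole $V(m)$ curve from a single distance
transform by thresholding the organ voxels' distances — voxel-identical to
expanding and intersecting margin by margin, because the organ lies inside
the grid and clipping of an expansion outside the field of view cannot
change its overlap with the organ. The standalone `expand_mask()` refuses
expansions that would leave the grid rather than silently truncating
(`pad_grid()` adds room).

Digitisation places the effective surface of a voxelised structure within
about half a voxel of the continuous one. A 20 mm sphere at 1 mm spacing
expanded by 10 mm lands within 2% of the analytic $\tfrac43\pi r^3$ volume;
smaller margins and erosions can deviate by a few percent in volume (the
half-voxel shift is relatively larger), which is the accuracy a user should
expect of any single voxel-counted volume at these spacings.

The 80%–20% falloff width (`falloff_width()`) averages dose over successive
1 mm expansion shells and reports the distance between the margins at which
the shell mean first drops below 80% and 20% of prescription. The shell
step is a resolution parameter, not a calibration input.

## What the phantom factory emulates — and what it does not

The synthetic module exists so that every statistical claim in the package
is testable without patient data. `make_phantom()` builds an ellipsoidal
lung (default semi-axes 62 x 64 x 66 mm, about 1.1 litres) and a curved
PTV: a spherical-shell sector (default 24 mm thick, 65 degrees half-angle)
wrapped around the lung's anterior surface across a chest-wall gap. The
shell's inner radius is set to the largest lung radius within the sector
cone plus the gap (default 4 mm), so the minimum lung–PTV clearance equals
the gap up to voxelisation. Voxels are 2 mm isotropic by default, which
keeps a full cohort pipeline at a few seconds per case on one CPU.

`conformal_dose()` assigns prescription inside the PTV and
$\mathrm{Rx} \cdot f(d)$ at distance $d$ outside, with $f$ piecewise linear
through anchors that place the 20 Gy(RBE) isodose exactly 11 mm and the
5 Gy(RBE) isodose exactly 22 mm outside the PTV at the 50.4 Gy(RBE)
reference. The $D$ isodose region is then *exactly* the PTV expanded by
$f^{-1}(D/\mathrm{Rx})$, voxel for voxel, under the shared threshold
conventions — so margin calibration on these phantoms has a known ground
truth (11 and 22 mm), and the noiseless cohort recovers it with RMSE at the
numerical floor. With the default geometry the base phantom's planned
$V_{20}$ is about 7% and $V_5$ about 24%, inside clinically reported
ranges.

`make_cohort()` adds inter-case variation: independent Gaussian
perturbations of the lung semi-axes, gap and shell thickness (scale
`jitter_mm`, default 1.5 mm, truncated to keep specs valid) and of the
interior falloff anchor distances (`dose_jitter_mm`, default 1 mm). The
geometric jitter spreads the per-case $V_D$; the falloff jitter varies
conformality from case to case, which is what gives the calibration a
nonzero RMSE and makes the convergence trace informative. These scales were
chosen once as plausible inter-patient anatomical and planning variation at
this voxel size.

What the phantoms deliberately do **not** reproduce: real CT densities and
heterogeneity corrections, beam-specific penumbra (uniform scanning vs
pencil beam scanning), breathing motion, hearts and other organs at risk,
and the irregular nodal target shapes of clinical cohorts. Passing the
phantom suites therefore demonstrates that the calibration machinery
recovers a known conformal geometry and that the implementation is
self-consistent — not that an 11 mm margin is the right clinical parameter
for any particular clinic, which only a planned-patient cohort can show.

`cold_spot_variant()` models the model's known failure mode: plans that
deliberately underdose part of the target (e.g. heart sparing for internal
mammary node coverage) by capping the dose inside a region. The contour
prediction cannot see the cap, so it overestimates the achieved lung
metrics — the direction the model errs in whenever conformality is
compromised. The cap is applied as `min(dose, floor)`; since $V_D$ uses a
closed threshold, a floor *equal* to the queried level still counts, so
demonstrations use floors strictly below it.

## File formats

Masks and dose travel as NIfTI-1 (geometry in the sform affine,
prescription in the description field), cohorts as YAML manifests, models
and calibration results as JSON, curves as CSV. DICOM RT support is
intentionally minimal — explicit VR little endian, axis-aligned identity
orientation, planar `CLOSED_PLANAR` contours — and implemented natively:
`read_rtdose()`/`write_rtdose()` round-trip 32-bit scaled dose grids, and
`read_rtstruct()` rasterises ROIs resolved through a configurable
name-pattern map. Oblique orientations, encapsulated transfer syntaxes and
RT-PLAN objects are out of scope.

## Known limitations

* The margin expansion is purely geometric; a water-equivalent
  (density-weighted) expansion would likely predict better across the
  soft-tissue/bone/lung interfaces but is not implemented.
* Calibration transfers only to plans whose conformality resembles the
  calibration cohort's; cold-spot plans are systematically overestimated.
* DVH queries use the empirical step convention; with coarse voxels,
  $D_V$ can differ from interpolating implementations by up to one DVH
  step.
* DICOM support covers the axis-aligned subset described above.
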