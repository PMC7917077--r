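---
title: "Methods: the Regional Aortic Weakness index and its numerical conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the Regional Aortic Weakness index and its numerical conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rawaaa)
```

This vignette documents what `rawaaa` computes, the assumptions behind each
stage, and — because a regional score built from quartiles and mesh
integrals is only reproducible if every convention is pinned down — the
exact numerical choices made. Default problem sizes (mesh resolution,
number of cycle phases, sample counts) are the package's own choices,
picked so that the synthetic verification fixtures resolve the planted
geometry; they are not clinical prescriptions.

## 1. The model in one paragraph

An abdominal aortic aneurysm (AAA) wall does not fail globally; it fails
at its locally weakest region. Three image-derivable surrogates of local
weakening are combined: intraluminal thrombus (ILT) thickness, because
thick thrombus is associated with wall hypoxia and degradation; maximum
principal Green–Lagrange strain over the cardiac cycle, because locally
compliant wall indicates altered structure; and time-averaged wall shear
stress (TAWSS), inverted, because low shear accompanies thrombus
deposition and sac growth. Each descriptor is area-averaged over 24 wall
patches, quartile-categorized, and combined into
`RAW = ((ILT_cat + STRAIN_cat + (5 - TAWSS_cat)) - 3)/9 * 10`,
a 0–10 score with a high/low cut at 6 (strictly greater is high).

## 2. Geometry: centerline and parcellation

`compute_centerline()` assumes a tube-like lumen. Nodes are binned by
projection onto the first principal (SVD) axis of the point cloud; each
non-empty bin contributes its node centroid; a moving-average pass
(half-width `smooth_window = 2` points) damps binning noise; and the
polyline is resampled at `n_samples = 50` equal-arclength points.

Two conventions matter:

- **Orientation.** The SVD axis sign is arbitrary, so the axis is oriented
  away from the end containing the mesh's first node. The convention
  depends only on the mesh, so the centerline — and with it the axial
  patch numbering — follows the mesh under any joint rigid motion.
- **End correction.** A single global axis cuts a curved tube obliquely
  near its ends, dragging end centroids sideways by up to one tube radius.
  The last `end_trim = 1` estimated tube radius of polyline at each end
  (radius estimated as the median node-to-polyline distance) is discarded
  and rebuilt by extrapolating a quadratic arclength fit over a window of
  about five tube radii of reliable interior. The quadratic captures the
  tube's curvature; a linear extension would miss it by the sagitta of the
  trimmed span. An earlier candidate design — iteratively re-slicing
  perpendicular to the current polyline — is documented here as a
  failure mode: for wide, tilted tubes the arclength of a cross-section's
  nodes varies with their lateral position, so kernel weights sample each
  ring asymmetrically and the bias *grows* with each iteration.

`assign_patches()` maps each wall face to one of `n_axial * 4` patches
(default `n_axial = 6`, hence 24). The axial index bins the face
centroid's nearest-centerline arclength into equal-arclength sections
(boundaries: `ceiling(arc/total * n_axial)`, clamped to `[1, n_axial]`).
The quadrant comes from the sign of the centroid's offset from its
centerline foot point projected on the patient axes; with the default
DICOM LPS axes, left is `+x` and posterior is `+y`. Tie rule: an offset
exactly on the left–right plane goes to `L`; exactly on the
anterior–posterior plane goes to `A`. `patch_average()` is area-weighted
and excludes `NA` faces from both numerator and denominator (missing
thickness is never imputed as zero).

## 3. Wall descriptors

### ILT thickness

`ilt_thickness()` defines thrombus thickness at a wall node as the mean
Euclidean distance to all lumen nodes within `radius = 5` mm (units are
mm throughout). Nodes with no lumen neighbor in range are `NA` — reported
missing, never zero. Two numerical caveats are intrinsic to this
definition:

- **Slant bias.** Averaging over a disc of neighbors overestimates the
  perpendicular gap, because off-axis neighbors are farther away. The
  bias is a function of gap/radius — roughly
  `E[sqrt(g^2 + t^2)] - g` over in-disc offsets `t` — so it is *not*
  reduced by mesh refinement and becomes O(radius) as the gap shrinks
  below the search radius. At gaps comparable to typical AAA thrombus
  (3–6 mm) with the default 5 mm radius it stays below typical mesh edge
  lengths, which is what the test fixtures assert. For a nearly exact
  perpendicular distance use `method = "nearest"`, an exact
  point-to-triangle distance to the lumen surface (it instead slightly
  *under*-reports across a faceted surface, by the chordal flattening of
  the mesh).
- **Cancellation near zero.** Pairwise distances use the expanded
  `|a|^2 + |b|^2 - 2 a.b` form for vectorization, which resolves
  coincident points only to about `sqrt(eps * |p|^2)` (~1e-6 at
  coordinates of order 100 mm). Irrelevant at thrombus scales.

### Strain

`principal_strain()` tracks each face across the cycle phases. For one
face, the in-plane deformation gradient is `F = H G^-1` with `G`, `H` the
reference/deformed edge matrices in local orthonormal frames, and the
reported value is the largest eigenvalue of the Green–Lagrange tensor
`E = (F'F - I)/2`, maximized over phases ("peak over the cycle, then
region-average", not the reverse). Vectorization computes, per face, the
largest eigenvalue of the generalized pair of 2x2 edge Gram matrices
`(H'H, G'G)`, whose eigenvalues equal those of `F'F`; strain is
`(mu - 1)/2`. Numerical convention: the generalized problem is reduced by
the Cholesky factor of the reference Gram matrix to a standard symmetric
2x2 solved as `(a + c)/2 + sqrt(((a - c)/2)^2 + b^2)`. The textbook
characteristic-polynomial discriminant is avoided deliberately: it
cancels catastrophically when the two eigenvalues coincide — exactly the
rigid-motion case a strain measure must send to zero — capping accuracy
at ~`sqrt(eps)` (~1e-8) instead of ~1e-14.

### TAWSS

`tawss()` integrates the WSS magnitude over one cardiac cycle by the
trapezoid rule with **periodic closure**: the last sample connects back
to the first over the implied closing interval, with the default period
`(t_n - t_1) * n/(n - 1)` for `n` uniformly indexed phases. With uniform
spacing this reduces exactly to the arithmetic mean of the magnitudes,
which is also the discrete convention used by the synthetic truth.
Magnitude is taken per phase before averaging (a sign-reversing
oscillatory shear has a large TAWSS, as intended; an oscillatory-shear
index is out of scope).

## 4. Categories and the score

`quartile_categories()` uses `stats::quantile(type = 7)` (the linear
interpolation default in R) and assigns 1–4 with boundaries inclusive on
the *lower* category: category increments only for values strictly above
Q1/Q2/Q3. The strict comparisons carry a 1e-9 relative tolerance so that
values identical up to machine noise tie; a degenerate distribution (all
values equal) therefore collapses to all-1, and fewer than four finite
values yields all-1 with a warning. The patient-specific and population
categories (the latter from a pooled table or a supplied `population`)
are averaged by `combined_quartile()`, giving half-integer categories in
`{1, 1.5, ..., 4}`. `raw_score()` applies the formula above;
`round_raw()` prints with half-up rounding to 2 decimals (base R's
`round()` is banker's rounding and would print some boundary scores
differently); `classify_raw()` uses a strict `> 6` cut. `raw_index()` is
the central fitting-style routine returning a classed object with
`print`/`summary`/`plot`/`as.data.frame` methods.

## 5. Ex vivo mechanics

`analyze_curves()` reduces uniaxial stress–strain records per sample and
loading direction. Ultimate tensile strength (UTS, MPa) is the running
maximum at the first sample where stress drops by more than
`drop_fraction = 0.02` below the running maximum (a rupture detector
robust to post-failure noise), falling back to the global maximum for
curves that end before failing. Hysteresis energy loss is
`100 * (A_load - A_unload)/A_load` with trapezoidal areas after sorting
by strain, the two branches trimmed to their common strain interval, and
the result clipped to [0, 100]. Tissue is classed *low* strength when
UTS < 0.3 MPa (strict). The curve generator plants both quantities
exactly: exponential loading and a power-law unloading whose exponent is
solved (by `uniroot`) so the planted area ratio is exact.

## 6. What the synthetic generator does and does not emulate

`make_aaa()` builds a structured triangulated tube (default 48 rings x 36
nodes, ~110 mm long, 11 mm neck radius, 27 mm sac radius): an outer wall,
a lumen offset inward by a parametric ILT gap (default: a Gaussian axial
bulge up to ~7.5 mm, thicker anteriorly), `n_phases = 10` tracked wall
positions over a 1 s cycle, and a per-face WSS series. It exists to give
every pipeline stage a closed-form truth:

- **Wall motion** is a spatially uniform radial stretch
  `lambda(t) = 1 + pulsatility * (1 - cos(2*pi*t/T))/2` (default
  pulsatility 0.03), so every face's true peak principal strain is
  exactly `(lambda_max^2 - 1)/2`. This is a deliberate restriction: a
  ring-varying amplitude would be more realistic but makes each face's
  map depend on two ring factors, destroying the exact closed form the
  strain oracle tests require. Consequence: within one synthetic patient,
  strain cannot differentiate patches (its category collapses to 1);
  cohort-level strain contrast comes from varying pulsatility across
  patients.
- **WSS** is a Poiseuille-like proxy, proportional to
  (neck radius / local lumen radius)^3 and directed axially with a
  pulsatile waveform — the right monotonicity (low shear in the dilated
  sac), not a flow solution.
- **Thrombus** is the planted wall–lumen gap itself, so the thickness
  estimator can be scored against truth, including which nodes must be
  reported missing.

`synth_cohort()` (default 9 patients) varies sac size, thrombus burden,
pulsatility and peak shear across patients, and plants per-patch tissue
strength with log-UTS decreasing in a standardized combination of thick
ILT, high strain and low shear, plus noise — ground truth for the
validation statistics, not a constitutive model.

## 7. Statistics

`compare_groups()`/`compare_multi()` gate on Shapiro–Wilk at 0.05 per
group: Welch t-test / one-way ANOVA when normal, otherwise a log
transform is attempted (all-positive data) and retested, otherwise
Mann–Whitney / Kruskal–Wallis. `correlate()` picks Pearson vs Spearman
the same way. `roc_auc()` computes AUC by the Mann–Whitney midrank
identity (ties between classes count 1/2) with a seeded,
class-stratified percentile bootstrap CI; the RNG state is saved and
restored around the bootstrap so calling it does not perturb a script's
random stream.

## 8. Limitations

- The WSS proxy and uniform stretch mean absolute synthetic descriptor
  values are plausible in scale but not patient-predictive; the package's
  claims are about the *measurement and scoring machinery*, verified
  against planted truth.
- The mean-distance ILT definition has the gap/radius slant bias above;
  comparisons across meshes are only fair at a fixed search radius.
- The centerline assumes one unbranched tube; bifurcations must be
  clipped upstream.
- Quartile categories make the score rank-based within patient and
  population: it is a prioritization index, not a calibrated probability
  of rupture.
- Mesh IO covers ASCII STL/PLY/legacy-VTK only; STL files carry no
  connectivity, so reading one welds duplicate vertices and does not
  preserve the writer's node numbering.
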