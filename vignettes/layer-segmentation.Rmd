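---
title: "Arterial-wall layer segmentation in microCT: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Arterial-wall layer segmentation in microCT: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`vesselct` segments the medial and adventitial layers of an artery imaged by
absorption microCT after paraffin embedding, and quantifies the resulting
label volume. This vignette records the model behind each stage, the
parameters that matter, and the design decisions that were genuinely open —
the information a maintainer needs to trust or change the defaults.

## The imaging model

A paraffin-embedded vessel presents four grey populations, in increasing
X-ray density: sub-paraffin pores, paraffin (background and lumen filling),
soft-tissue ground (interlamellar cells, adventitial collagen matrix), and
dense fibrous features (elastic lamellae; collagen fibre bundles). The media
and adventitia overlap almost completely in mean grey value; what separates
them is *organisation*. The media's lamellae are concentric, nearly closed
rings; the adventitia's fibres are short and randomly oriented. After
unwrapping the wall around the lumen, lamellae become near-vertical lines
while adventitial features stay short and obliquely oriented — a difference
a 1D vertical morphological opening can exploit.

Assumptions worth stating explicitly:

* **one simple lumen per slice** — bifurcations and collapsed lumens are out
  of scope; a slice whose lumen cannot be traced is flagged for manual
  review, not guessed;
* **star-shaped wall** about the lumen centroid (used when the boundary is
  re-wrapped into a label image); strongly eccentric or folded walls violate
  this;
* **near-radial unwrap normals** — thickness is measured along unwrap
  normals, which for near-circular vessels coincides with the radial
  direction classically used for wall measurements;
* the **adventitial ground is slightly denser than paraffin but darker than
  the texture threshold**. This is the property that makes the adventitia
  fragment under thresholding while the media stays solid, and it drives the
  two-threshold scheme below.

## Two thresholds, not one

The pipeline computes, per slice, an Otsu *texture threshold* on the
unwrapped image (separating bright ordered features plus interlamellar
tissue from everything darker) and then a darker *wall threshold* from a
second Otsu pass restricted to the sub-texture-threshold population
(separating paraffin from adventitial ground). The texture threshold feeds
the opening/edge-profile/geodesic chain; the wall threshold defines the
outer wall edge and the lumen interface. Collapsing both into one threshold
either dissolves the adventitia entirely (threshold too high) or makes it a
solid band indistinguishable from media (too low); the two-stage scheme is
the package's resolution of that tension.

## Stage-by-stage notes and parameters

**Axial bilateral filter** (`bilateral_filter_axial`): window 7 voxels,
spatial SD 1.5 voxels, range SD defaulting to a robust noise estimate
(1.4826 x median |axial first difference| / sqrt(2)). Filtering only along
the axis preserves every trans-axial boundary exactly; window truncation at
the stack ends means a single slice passes through unchanged.

**Lumen edge** (`detect_lumen_edge`): marching-squares iso-contour at the
wall threshold, keeping the smallest closed contour enclosing the centre
hint (default: centroid of below-threshold pixels). The contour level is
then refined to half-way between the lumen interior mean and the *lower
quartile* of the band 1.5-4 voxels outside the contour, and retraced. The
half-contrast level makes the traced interface unbiased on blurred edges;
the lower quartile guards against the first lamella leaking into the band in
thin-walled vessels. A disk without a hole, or a hint on tissue, raises
"lumen not found".

**Periodic spline** (`fit_lumen_spline`): cyclic penalised regression
splines for x(t) and y(t) against normalised chord length (basis dimension
16, smoothing parameter 1; smoothing 0 switches to exact periodic cubic
interpolation). The deliberately small basis caps the angular frequency the
anchor curve can follow: luminal ripples of ~10+ cycles have radii of
curvature of a few voxels, and an anchor that followed them would have
crossing outward normals inside the wall. The spline therefore tracks the
overall lumen shape, while per-row ripple detail is recovered later by
sub-voxel refinement. Self-intersecting fits are rejected.

**Unwrapping** (`unwrap_slice`/`rewrap_points`): rows sample equal arc
intervals (360 rows per slice by default, so all slices share a grid for 3D
smoothing); columns are signed normal offsets with a 5-voxel inner margin
and 80-voxel outer depth (covering the default wall of ~60 voxels plus
paraffin). Re-wrapping is the closed-form inverse (anchor point + offset x
normal), not a numeric inversion. Row-wise the area Jacobian is 1 on the
spline; radially it scales as (1 + offset x curvature) — voxel counting in
the unwrapped frame understates ring area accordingly, which is why all
areas are measured in the trans-axial label volume instead.

**Texture filtering** (`open_vertical`, `remove_islands`): opening with a
9-row vertical line element; island removal at 60 px (8-connected). The
element length trades lamellar slope tolerance (wavy lamellae are locally
oblique) against fibre suppression; 9 rows keeps lamellae with waviness
slopes up to ~0.3 voxel/row connected. The island threshold does most of
the fibre rejection: after opening, fibre remnants are small isolated
blobs, while even a fragmented lamella remains one large 8-connected ring.

**Edge model** (`fit_edge_model`): the per-row candidate boundary position
is `x_e + 1` — one step outward of the outermost retained wall pixel, i.e.
the first pixel outside the wall. A 2-component Gaussian mixture (EM,
deterministic quantile initialisation, 200 iterations or log-likelihood
change < 1e-8, variance floor 1e-4) separates the boundary population from
rows corrupted by residual adventitial features; the dominant (largest
weight, ties to the smaller mean) component supplies the mean edge position
and the default closeness tolerance of twice its SD.

**Weight image and geodesic** (`build_weight_image`,
`trace_geodesic_boundary`): base weight 1, edge bonus 2 at qualifying
candidate pixels, mask penalty 0.5 inside the initial thresholded image
(penalty applied before bonus; weights clipped at zero). The boundary is the
exact minimiser of total cost (W_max − W) plus lambda x |column step|, with
steps bounded by d_max = 2 and the closure across the row wrap penalised
(not bounded). Defaults: lambda = 0.5 x bonus / d_max = 0.5. The optimum is
found by dynamic programming conditioned on the start column
(O(rows x cols^2 x d_max), in C++); ties break toward smaller column
indices everywhere, so results are bit-reproducible. Whether the original
formulation meant continuous fast marching or this layered-graph shortest
path is immaterial up to discretisation — the two are equivalent for a
row-monotone path, and the discrete optimum is verified against exhaustive
path enumeration in the test suite.

**Sub-voxel refinement and 3D smoothing**: the integer geodesic sits on the
first pixel outside the wall, i.e. up to ~1.5 voxels outside the true
interface once PSF blur and threshold level are accounted for. Each row is
therefore refined to the first half-contrast crossing of the outward
intensity profile within +/-4 columns (local plateau medians for the
boundary; a fixed per-slice level — midway between the global paraffin and
adventitial-ground medians — for the outer wall edge, where local windows
are fibre-contaminated). Rows without a valid crossing become missing and
are filled by periodic interpolation. The boundary and outer-edge surfaces
are then smoothed with a separable Gaussian over (arc row, slice) — SD 3
rows x 2 slices, circular in rows, reflected in slices. Without refinement
the noiseless cross-sectional-area recovery would be biased by several per
cent; with it the acceptance script measures errors of ~1% or less.

**Morphometry**: thickness per row = boundary minus lumen-edge column (x
voxel size), per-slice value = mean over rows; CSA = voxel count x voxel
size squared, so the per-slice class areas sum *exactly* to the slice area;
axial length = slice count x voxel size, rounded to the nearest micrometre
(450 slices at 0.75 um report 338 um). Pores are voxels darker than
paraffin mean − 3 SD (background median/MAD estimate) inside the wall's
filled hull (per-slice disc closing, radius 5), grouped 26-connectedly, with
a 9-voxel minimum size. Group comparison uses a Welch t-test over slices
(the original report names no test); the output carries an explicit caveat
that slices are spatially autocorrelated and p-values therefore
anti-conservative — a correction is out of scope.

## The phantom: what it emulates, and what it does not

`make_vessel_phantom` renders the tissue architecture the pipeline targets:
a paraffin-filled lumen with axially oriented surface ripples (radius
modulation constant along the axis), concentric wavy lamellae (per-lamella
random phase), interlamellar ground, an adventitia of darker ground
scattered with short bright fibre segments (length 5-15 voxels, random
orientation), spherical sub-paraffin pores placed uniformly in the
adventitial annulus (no overlap testing — overlaps merge), Gaussian PSF
blur (SD 0.7 voxels) and additive Gaussian noise. Ground-truth labels and
analytic per-slice metrics come from the pre-blur geometry: blur and noise
are measurement effects, not anatomy. Default grey levels are pore 20,
paraffin 60, adventitial ground 85, interlamellar 120, fibre 170, lamella
200 — ordered as the tissue contrasts require (only pore < paraffin <
interlamellar is enforced; the rest is configurable). The default lamellar
count (5) is a placeholder typical of a small muscular artery, not a
measured value.

What the phantom does *not* model — and what passing tests therefore cannot
show: beam hardening and ring artefacts, non-Gaussian or correlated noise,
intensity inhomogeneity across the field, true fibre micro-architecture,
eccentric or collapsed lumens, and any skin-like geometry. Real tomograms
with locally poor contrast will still need the flag-and-review path that
replaces interactive touch-up here.

The pressurised variant (`make_pressurised_pair`) applies multiplicative
factors — lumen radius 1.22 (chosen to match a reported lumen-CSA ratio of
~1.49), layer thickness 0.85, ripple and waviness 0.4, pore count 0.3 — so
that the pressurised member has, by construction, a larger lumen CSA,
thinner layers, straighter lamellae, a smoother luminal surface and fewer
pores. These are direction-setting defaults, not measurements.

## Problem sizes and determinism

The validation suite runs entirely on generated data: 20 phantoms of
256 x 256 x 64 voxels at noise SD 21 (15% of the lamella-paraffin contrast)
for segmentation recovery; a noiseless phantom of the same size for
thickness/CSA/pore recovery; a 48-slice pair for the pressurisation
directions; 100 random 12 x 12 weight images against exhaustive path
enumeration; 256^2 slices for the unwrap round trip. These sizes were
chosen as the smallest at which the geometry is representative of the
default vessel (a ~40-voxel-thick wall needs a ~256-voxel field). Every
stochastic stage takes an explicit seed; identical configuration and seed
give byte-identical label and contour outputs, which the I/O tests verify
via checksums.

## Known limitations

* The boundary definition inherits the `x_e + 1` convention: the interface
  is the first position outside the outermost lamella. A systematic
  quarter-voxel outward offset relative to the geometric lamella edge
  survives refinement under noise.
* Lumen-edge refinement assumes some darker tissue immediately outside the
  lumen; when the innermost lamella touches the lumen within ~2 voxels the
  contour can bias outward by a fraction of a voxel.
* The unwrap-based thickness is a normal-ray measurement; for strongly
  eccentric lumens it differs from nearest-boundary Euclidean thickness.
* p-values from `summarize_groups` treat slices as independent; they are
  best read as descriptive within a specimen.
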