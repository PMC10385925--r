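---
title: "CT morphometry of the canine adrenal gland: models, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CT morphometry of the canine adrenal gland}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`adrenomorph` quantifies adrenal gland size and attenuation from
contrast-enhanced abdominal CT and reproduces the downstream cohort
statistics used to derive weight-stratified reference intervals for healthy
dogs. This vignette documents the models, the measurement conventions, the
numerical choices, and what the synthetic validation does and does not
establish.

## Slice-addition volumetry

Gland volume is computed from a binary segmentation mask by the
slice-addition technique (SAT): within each slice the number of segmented
voxels is multiplied by the single-voxel volume, and the slice partial
volumes are summed. Because every voxel contributes exactly its own volume,

$$V \;=\; N_{\text{voxels}} \cdot s_x s_y s_z,$$

independent of the slicing axis. `compute_volume()` therefore computes the
total directly from the voxel count and retains the per-slice decomposition
(as integer voxel counts and as partial volumes) purely for reporting; the
per-axis totals agree exactly because the counts are integers.

Digitization follows the voxel-center convention: a voxel belongs to the
shape when its center lies inside, the same counting model a manual
segmentation approximates. On ellipsoids the digitization error of SAT falls
below 1% once in-plane spacing reaches 0.2 mm for semi-axes of 3 mm or more;
the convergence table produced by `analysis/02_phantom_validation.R` tracks
this.

Masks are taken as given: excluding the phrenicoabdominal vessels is the
segmenter's responsibility, and no partial-volume correction is attempted.

## 3D-ROI attenuation and the homogeneity screen

`mean_attenuation()` averages Hounsfield units over exactly the voxels used
for volumetry — the whole organ including boundary voxels. The mean equals
the naive sum divided by the count to within 1e-9 relative accumulation
error. Inclusion criteria for healthy glands require homogeneous contrast
distribution; since that criterion is qualitative in clinical practice, the
package flags a gland as homogeneous when the ROI standard deviation does
not exceed a configurable threshold (default 25 HU, set above the HU noise
expected of a uniformly enhancing soft-tissue ROI at abdominal CT so that
only clearly bimodal or patchy enhancement trips it). This SD screen is a
stand-in, not a validated criterion, and is exposed as `sd_threshold`.

## Surface extraction

`extract_surface()` builds the exact boundary of the voxel solid: every face
of an occupied voxel adjacent to background becomes an outward-oriented
quad, split into triangles. The mesh is closed and watertight by
construction and the enclosed volume (divergence theorem) equals the SAT
volume identically — the mesh is an exact geometric dual of the counting
model rather than a smoothed isosurface. The Euler characteristic of the
mesh is 2 for well-composed genus-0 masks, which is what healthy gland
segmentations and all shipped phantoms produce. Meshes export as ASCII
PLY/OBJ.

## Gland-frame caliper measurements

The measurement protocol adjusts the transverse plane orthogonally to the
gland's maximal craniocaudal axis before taking calipers. The package
formalizes each step:

* **Length** is the maximum Euclidean distance between occupied voxel
  centers (exact 3D farthest pair over boundary voxels, computed in C++).
  This is the rotation-invariant formalization of seeding a 3D length tool
  on the gland surface in a sagittal view; whether the original protocol
  constrained the chord to the sagittal projection is unknowable from the
  protocol description, and the farthest-pair definition is the one that
  survives arbitrary patient pose. The divergence is deliberate and tested
  (rotating a phantom changes the measured length by under 2%).
* **Frame**: the length axis points cranial-to-caudal; the in-plane
  dorsoventral axis is the anatomical DV direction projected onto the plane
  orthogonal to the length axis and renormalized (minimal-rotation
  convention); the mediolateral axis completes the right-handed triad.
  Anatomical axis labels are explicit inputs (`axes = c("CC","DV","ML")`),
  never guessed from file orientation, because exported veterinary CT
  orientation metadata is unreliable and the patient may lie in dorsal or
  ventral recumbency.
* **Reorientation** resamples the mask isotropically at the smallest
  original spacing, interpolating occupancy trilinearly and thresholding at
  0.5. Volume changes by well under 1% on isotropic masks.
* **Poles and isthmus**: clinical protocols measure "in the cranial and
  caudal pole" and "at the isthmus" without an operational rule, so the
  package scans cross-sectional areas along the length axis: the cranial
  pole is the maximal-area station within the cranial half (window
  configurable via `pole_window`, default 0.5), ties broken toward the
  cranial end; the caudal pole symmetrically; the isthmus is the
  minimal-area station strictly between the poles, ties broken toward their
  midpoint. On a uniform cylinder this places poles at the end stations
  with the isthmus area equal to the pole area; on a monotone cone the
  isthmus hugs the narrow pole.
* **Height and width** are axis-aligned extents of the station's
  cross-section along DV and ML, measured voxel-center to voxel-center plus
  one voxel — matching calipers drawn along the anatomical axes of the
  adjusted plane rather than a maximal rotating caliper. Isthmus calipers
  are reported for the left gland only, following the protocol. Because the
  caliper convention is edge-inclusive while the farthest pair is
  center-to-center, a perfect sphere can show H exceeding L by up to one
  voxel; the measurement container grants exactly that one-voxel-diagonal
  slack and otherwise enforces H, W ≤ L.

The dorsoventral aortic diameter is the DV extent of the aorta mask at a
user-supplied transverse station; locating the landmark (caudal to the
cranial mesenteric artery) is the operator's task.

## Size indices and reference intervals

The **ratio volume–aorta** normalizes gland size by body size:

$$\mathrm{RVA} = \frac{\sqrt[3]{V\ [\mathrm{mm^3}]}}{D_{\text{aorta}}\ [\mathrm{mm}]},$$

dimensionless and invariant under isotropic body scaling
($V \to s^3 V$, $D \to sD$). Volumes enter in cm³ at the interface and are
converted internally.

The **between-breed coefficient of variation** of a caliper metric is the
sample standard deviation (n−1 denominator) of the breed mean values divided
by their arithmetic mean. Unrounded values are always retained; tables
display 2 decimals. Two of the twelve published CV rows sit within 0.005 of
a rounding boundary (isthmus height, left cranial height), so their printed
2-decimal values depend on whether the original computation used rounded or
unrounded breed means; the package documents this rather than forcing
agreement.

**Correlation strength** bands |r| as very weak [0, 0.2), weak [0.2, 0.4),
moderate [0.4, 0.6), strong [0.6, 0.8) and very strong [0.8, 1], ignoring
sign.

**Weight classes** split at 20 kg; exactly 20.0 kg is heavy (the boundary
case is not addressed clinically, and the rule here is total and
deterministic).

**Reference tables** report, per weight class × side × metric, the 10th
percentile, quartiles and 90th percentile with the stratum size. Percentiles
default to linear interpolation between order statistics
(`stats::quantile` type 7); the statistics suite that produced the original
reference values may use a different definition, so the type is exposed
(`qtype`) instead of being guessed. Strata under the minimum size (default
5) are omitted with a warning. `assess_against_reference()` additionally
compares the left caudal-pole height against the legacy weight-independent
7.4 mm threshold, the comparison the stratified intervals are meant to
replace.

## The statistical battery

All tests default to α = 0.05.

* **Normality gate**: Shapiro–Wilk with p ≥ α meaning "treat as normal".
  The original analysis does not state whether the gate was applied per
  group or pooled; the default is per group (every breed must pass), with
  `gate = "pooled"` available for gating the centred residuals instead.
* **Breed comparison**: if the gate passes, one-way ANOVA with REGWQ letter
  grouping; otherwise Kruskal–Wallis with letters from pairwise two-sample
  Wilcoxon tests. The pairwise tests are *protected* — consulted only when
  Kruskal–Wallis rejects — mirroring the reporting order of the clinical
  analysis (a global p first, then pairwise p-values) and keeping the
  familywise error of the nonparametric branch near α. Pairwise p-values
  are raw by default (`p_adjust = "none"`), again mirroring clinical
  reporting; any `p.adjust` method can be switched on.
* **REGWQ** (`regwq()`): step-down multiple range test on the ordered
  means. A range of p adjacent ordered means is tested at
  $\alpha_p = 1-(1-\alpha)^{p/k}$ for $p \le k-2$ and at $\alpha_p=\alpha$
  for $p \in \{k-1, k\}$, with studentized-range critical values at the
  pooled error degrees of freedom; a non-rejected range is homogeneous and
  its sub-ranges are never tested. Unequal group sizes use the harmonic
  mean of the sizes within the range (the classical unequal-n adaptation;
  the choice is documented because range tests have no canonical unequal-n
  form). Letters encode maximal homogeneous ranges, so two groups share a
  letter exactly when the procedure never declared them different — an
  invariant the test suite checks structurally on randomized inputs. With
  two groups the procedure reduces to the pooled two-sample t-test. Under a
  6-group global null its empirical familywise error sits at α.
* **Side tests**: paired t on left−right differences when the differences
  pass the gate, Wilcoxon signed-rank otherwise; identical pairs
  short-circuit to "no difference".
* **Weight-group tests**: two-sample Wilcoxon rank-sum between light and
  heavy classes.
* **Correlations**: Pearson r with the two-sided test and the strength
  band.

Degenerate inputs are rejected with named errors: constant samples at the
gate, groups below minimum size (naming the offending group), unpaired
records, empty weight classes, constant correlates.

## The synthetic cohort

Since no per-dog clinical data are deposited anywhere, the simulator is the
package's test bed. It emulates the published 66-dog design — six breeds
with sample sizes (16, 10, 8, 14, 12, 6), sex/neuter composition, and age
and weight means/SDs per breed — and draws:

* **weights** from truncated-positive normals per breed;
* **volumes** per side from the allometric model
  $V = a W^b e^{\varepsilon}$, $\varepsilon \sim N(0, \sigma^2)$, with a and
  b fit once by least squares of log mean volume on log mean weight over
  the six published breed pairs (b ≈ 0.49 left, 0.51 right) and σ set from
  the mean published within-breed coefficient of variation (≈ 0.23). This
  is calibration to published summaries, not ground truth;
* **aortic diameters** from $D = c W^d e^{\delta}$, with c and d solved
  from the two weight-class RVA medians at the class mean weights
  (d ≈ 0.38) and σ(δ) set so the population correlation between log
  diameter and log weight matches the published 0.82;
* **caliper metrics** as shape factors times the cube root of the gland's
  volume with multiplicative lognormal noise; factors are the mean ratio of
  published metric means to the cube root of the published volume means,
  and the residual noise completes each metric's published within-breed CV
  beyond what the volume noise already conveys;
* **attenuation** with the left gland from the published breed mean/SD and
  the right gland as left + published breed side offset + N(0, 6 HU),
  giving the paired side structure that signed-rank tests detect.

A master seed fans out into per-dog substreams, so enlarging a cohort never
changes earlier dogs, and identical seeds give identical cohorts.

The simulator reproduces the *statistical structure* the analysis assumes —
allometric scaling with realistic scatter, weight-class separation of RVA,
breed-level volume separation, side-offset attenuation. It does not emulate
partial-volume effects, contrast-timing pharmacokinetics, organ-shape
variation (phantoms are parametric solids, not shape atlases), or
inter-observer segmentation variability. Volume and aortic-diameter
residuals are drawn independently; if in real dogs both scale together with
body size beyond what weight explains, real RVA reference intervals will be
narrower than simulated ones (the simulated medians match published values
more closely than the simulated 90th percentiles do). Passing tests therefore validate
the measurement and inference machinery, not the clinical accuracy of any
particular reference value; reference tables built from simulated cohorts
are structural stand-ins, not clinical intervals.

Phantoms (`make_phantom()`) provide the imaging-side ground truth:
ellipsoids, cylinders and dumbbells (two spherical lobes joined by a
cylindrical neck — a gland-like shape with an unambiguous isthmus) with
closed-form volume, length and cross-section dimensions, at the default
CT-like spacing of 0.2 × 0.2 × 2 mm or any other.

## Numerical choices

* In-plane resampling (to the harmonized 0.2 mm pixel) interpolates
  bilinearly within each slice, preserving the through-plane sampling. New
  sample positions are aligned to the *edges* of the old field of view, so
  refining a lattice never places samples exactly on occupancy midpoints;
  with midpoint sampling, thresholding at 0.5 would systematically dilate
  masks (a ~2% volume bias on a 5 mm sphere refined 0.4 → 0.2 mm), while
  edge alignment keeps the resampled volume within a fraction of a percent.
  Masks are interpolated as real fields and thresholded at 0.5
  (trilinear-then-threshold, not nearest neighbour, to reduce
  stairstepping), which keeps outputs strictly binary and bit-reproducible.
* Coordinates are voxel-center based throughout: voxel i spans
  [i·s − s/2, i·s + s/2).
* Ties in pole/isthmus location break toward the respective gland end
  (poles) and toward the inter-pole midpoint (isthmus), making the
  procedure deterministic.
* Shapiro–Wilk caps at n = 5000; larger samples are thinned with a
  deterministic even stride.
* With zero pooled variance REGWQ treats equal means as homogeneous and
  distinct means as separated, avoiding 0/0.

## Problem sizes

The shipped validation uses ellipsoid phantoms at 0.2 mm isotropic
(~1.6 × 10^5 foreground voxels), dumbbell pose-invariance at 0.4–0.5 mm,
2000 replicates for the REGWQ null level, 200 replicates for the calibrated
breed-separation check, and 60 seeds of n = 500 cohorts for allometric
recovery — sizes at which all Monte-Carlo margins in the tests are several
standard errors wide.

## Known limitations

* NIfTI is the supported volume format; DICOM series are not read (the
  rescale arithmetic a DICOM backend would need is provided as
  `hu_rescale()`).
* The surface mesh is the exact voxel boundary, not a smoothed isosurface;
  rendering-quality meshes are out of scope.
* Automatic segmentation, landmark detection (cranial mesenteric artery)
  and any diagnostic claims about hyperadrenocorticism are out of scope.
* The homogeneity screen and the pole/isthmus localization rule are
  operationalizations of qualitative clinical conventions and are exposed
  as configuration rather than asserted as the original protocol.
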