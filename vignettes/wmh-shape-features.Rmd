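---
title: "Quantifying white matter hyperintensity shape and location"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying white matter hyperintensity shape and location}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmhshape)
```

## The problem

White matter hyperintensities (WMH) on FLAIR MRI are the key imaging marker
of cerebral small vessel disease, but they are almost always summarized by a
single number, total volume. Volume is etiologically blunt: different disease
processes produce lesions of different *shape* (spherical punctuate dots,
elongated early-confluent caps, irregular confluent sheets) and different
*location* (periventricular versus deep, and per lobe). `wmhshape` implements
a per-lesion 3D shape and location feature pipeline for binary WMH
segmentation masks, together with the cohort-level statistics needed to
compare two groups, and a synthetic phantom/cohort generator that provides
geometric and statistical ground truth for every stage.

The pipeline is: individual lesions are separated by 26-connected component
labeling; lesions of fewer than 5 voxels are excluded (at a typical
0.96 x 0.96 x 3.00 mm FLAIR grid this is the printed < 0.014 ml bound —
shape analysis is meaningless at that size); each lesion is converted to a
closed triangular surface mesh; shape features are computed per lesion;
lesions are classified as *punctuate deep* (more than 1.0 cm from the
ventricles **and** maximum diameter under 1.5 cm, both strict) or
*non-punctuate* (periventricular and confluent lesions pooled), with manual
overrides supported; punctuate-deep lesions get a lobe label and can be
accumulated into per-voxel mean eccentricity maps.

## Shape features

With mesh volume $V$ (mm^3), surface area $A$ (mm^2), axis-aligned bounding
box extents $d_x, d_y, d_z$ and principal curvatures $k_1 \ge k_2$:

* **Eccentricity** $= D_{max} / D_{min}$, where $D_{max}$ is the largest 3D
  caliper diameter (maximum vertex-pair distance) and $D_{min}$ the smallest
  orthogonal width: vertices are projected on the plane orthogonal to the
  $D_{max}$ direction and the extent is minimized over a 1-degree grid of
  in-plane directions. 1 means spherical; ~4 means strongly ellipsoidal.
  Translation-, scale- and rotation-invariant.
* **Compactness1** $= V^2/A^3$, bounded above by the isoperimetric constant
  $1/(36\pi) \approx 0.00884$ (attained by a sphere).
* **Compactness2** $= V/(d_x d_y d_z)$ and **Compactness3** $= V/d_{max}^3$
  with $d_{max} = \max(d_x, d_y, d_z)$; both in $(0, 1]$. The extents are
  taken along the *image axes*, which is what makes 1 the attainable ceiling
  (an axis-aligned box).
* **Fractal dimension**: box counting over the lesion's boundary voxels
  (lesion voxels with a 6-connected background neighbour), with cubic boxes
  of side $1, 2, 4, \ldots$ voxels anchored at the bounding-box corner.
  The dimension is the least-squares slope of $\log N(s)$ against
  $\log(1/s)$.
* **Shape index** $= \frac{2}{\pi}\arctan\frac{k_1+k_2}{k_1-k_2} \in [-1,1]$
  and **curvedness** $= \sqrt{k_1^2+k_2^2}$, evaluated per lesion voxel and
  summarized by the median over voxels with defined curvature.

Curvatures are isophote curvatures from the Gaussian-derivative gradient and
Hessian at scale $\sigma = 1$ voxel, via the standard implicit-surface
formulas for mean curvature $H$ and Gaussian curvature $K$ and
$k_{1,2} = H \pm \sqrt{\max(H^2-K, 0)}$.

## Design choices where the method is underdetermined

Several details are not pinned down by the published description; this
package's choices are:

* **Meshing.** The surface is extracted at iso-level 0.5 of the binary
  lesion sub-volume, zero-padded by one voxel (so surfaces are closed even at
  the image border), in index space; vertices are scaled to mm by the voxel
  spacing afterwards, concentrating all anisotropy handling in one place.
  Rather than the classic marching-cubes case table — whose ambiguous
  configurations can produce cracked or non-manifold surfaces exactly in the
  corner-touching voxel patterns that 26-connectivity admits — the mesher
  builds marching-squares contours on each cell face (a fixed saddle rule
  separates diagonal foreground corners), chains them into closed loops per
  cell and fan-triangulates each loop from its centroid. Because the face
  rule depends only on the shared face values, adjacent cells always agree,
  and the mesh is watertight and consistently oriented *by construction* for
  every binary input. On a digital ball of radius 10 voxels the mesh volume
  and surface area agree with the analytic sphere within the 5% and 10%
  tolerances the test suite asserts, comparable to standard marching-cubes
  implementations on binary data.
* **Labeling order.** The published method meshes the whole segmentation and
  then splits lesions by voxel 26-connectivity; we label voxels first and
  mesh per lesion. At iso 0.5 with padding, marching-style meshing creates no
  surface between 26-disconnected voxel sets, so the resulting partition is
  the same and the bookkeeping is simpler.
* **Size filter.** Counts voxels (< 5 excluded); the printed "< 0.014 ml" is
  the 5-voxel rule expressed at the study's voxel size, not an independent
  threshold.
* **Diameters.** $D_{max}$ is the exact vertex-pair caliper (tie-break:
  lexicographically smallest index pair). For very large meshes (beyond
  2000 vertices) the search is restricted to directional extreme points,
  which bounds the error by the direction-grid resolution (~0.2%); all
  small-mesh paths are exact and tested against brute force. "Smallest
  diameter orthogonal to the largest" is read as the minimal projected
  *width*, the rotation-invariant choice, on a 1-degree grid.
* **Curvature units and image.** Derivatives are taken in index space with
  $\sigma$ in voxels, so curvature carries 1/voxel units and slice-thickness
  anisotropy is deliberately *not* corrected — this mirrors the stated
  "scale = 1 voxel" convention. By default the "image" is the lesion's own
  binary mask (self-contained and deterministic); a co-registered scalar
  image can be substituted. At umbilic points ($k_1 = k_2$) the shape index
  takes its analytic limit $\mathrm{sign}(k_1)$, and 0 when both curvatures
  vanish; voxels with gradient magnitude below 1e-8 are flagged undefined
  and excluded from the medians.
* **Box-counting scales.** A single grid origin at the bounding-box corner
  (no offset averaging), box sides powers of two, and only scales strictly
  below half the maximal extent: at $s = \mathrm{ext}/2$ every box intersects
  a closed surface (8 of 8), which carries no information and visibly
  inflates the slope (2.37 instead of 2.23 for a 32-voxel cube shell). With
  fewer than 3 usable scales the value is flagged undefined rather than
  extrapolated — a 5-voxel lesion has no meaningful fractal dimension.
* **ICV correction.** Surface area is divided by intracranial volume in ml
  (ratio normalization, declared as the unit convention).
* **Ventricle distance.** Minimum over lesion voxels of an exact
  anisotropy-aware Euclidean distance transform, i.e. the *whole lesion*
  must lie beyond 1 cm — the conservative reading. Both classification
  inequalities are strict, so threshold-exact lesions are non-punctuate.
* **Lobes.** Majority label over lesion voxels, ignoring background; ties
  break in the fixed order frontal > parietal > temporal > occipital >
  basal ganglia region > cerebellum; all-background lesions take the nearest
  labelled voxel. Basal-ganglia-region and cerebellum labels are kept in the
  records for lossless accounting even though report tables conventionally
  drop them.

## Cohort statistics

Per subject and per stratum (all / non-punctuate / punctuate-deep):
total lesion volume as %ICV, lesion count, and the median per-lesion
eccentricity. Volumes are scaled by 10000 and natural-log transformed (the
scaling keeps the transformed values positive so the direction of effect is
retained); counts are log transformed; eccentricity is analyzed raw.
Group differences use OLS adjusted for age and sex; `b` is the raw group
coefficient with a t-based 95% CI and `beta` standardizes it by
SD(indicator)/SD(outcome), the CI scaled identically. Subjects with an empty
stratum drop out of that stratum's regressions (log of zero), which is why
stratum n's can fall below the cohort n. Per-lobe count comparisons use 2x2
chi-square tests without continuity correction (counts are the sufficient
data; testing literal percentages is ill-defined), with full-precision and
half-up-rounded percentages reported side by side; per-lobe eccentricity
uses two-sided Mann-Whitney U. Distribution summaries report mean, min, max,
Fisher's moment skewness $g_1$, and a one-sample Kolmogorov-Smirnov p-value
against a normal with the sample mean and SD — with estimated parameters this
is the anti-conservative textbook variant (a Lilliefors-type situation), kept
deliberately and flagged as approximate. No multiple-testing correction is
applied anywhere.

## The synthetic generator: what it does and does not emulate

`make_phantom()` produces analytic digital shapes (spheres, ellipsoids,
boxes, rods, blobs) by voxel-center inclusion, so every geometric feature has
a closed-form truth. `make_toy_atlas()` builds two paramedian box
"ventricles" and a fixed-plane lobe parcellation (+y anterior, +z superior:
frontal/parietal above the axial midplane, temporal/occipital below, plus a
central basal-ganglia box and an inferior-posterior cerebellum block) on a
default 128 x 128 x 64 grid at 1 x 1 x 3 mm — deliberately the thick-slice
regime of 2D FLAIR protocols.

`make_cohort()` draws, per subject, Poisson(12) punctuate-deep ellipsoids
(the published per-subject median count) and Poisson(6) non-punctuate
ventricle-abutting blob unions for controls (scaled down from the published
median of 26 to what the toy grid can host without everything merging), with
a patient rate ratio of 1.5 for non-punctuate counts and an additive patient
shift (default +0.4) of the log-elongation of punctuate lesions — the
direction and order of magnitude of the published group findings. Elongation
is lognormal (meanlog log 1.75, sdlog 0.3, matching the published punctuate
eccentricity percentile spread); the ellipsoid minor diameter is drawn from
4.5-6.5 mm and shrunk (floor 3.2 mm) when needed to keep the major diameter
at most 11.5 mm, because voxelized surfaces inflate by up to half a voxel
(1.5 mm on 3 mm slices) per end and the 15 mm classification rule is strict.
Punctuate centers are kept more than 23 mm from the ventricles and mutually
16 mm apart, so intended punctuate lesions satisfy the classification rule
with margin and never merge; blobs may merge with each other, and merged
units keep one identity with their per-lesion ground truth dropped.
Demographics: age ~ N(71, 4.5) truncated to 65-80, 58% male, ICV ~
N(1450, 120) ml. Everything is reproducible from the single seed.

What the generator does **not** emulate: FLAIR intensities (no noise or bias
fields — curvature features default to the mask), real ventricle and lobe
anatomy, registration error, segmentation error, spatially varying lesion
prevalence, and within-subject correlation of lesion shapes. Passing the
recovery suites therefore demonstrates that the *measurement and inference
chain* is correct on data whose truth is known — not that the features are
accurate on clinical images.

## Validation studies and the problem sizes used

The test suite runs entirely on generated data:

* geometric oracles on phantoms (exhaustive-search calipers, 0.1-degree
  width grids, isoperimetric bounds, analytic curvature surfaces, box
  counting on lines and cube shells);
* a classification invariant checked exhaustively on generated cohorts:
  every punctuate-deep label satisfies the strict distance/diameter rule;
* parameter recovery: 50 seeds of n = 100/group cohorts with the +0.4
  log-elongation patient shift, requiring the age/sex-adjusted regression to
  detect a positive standardized effect at p < 0.05 in at least 90% of
  seeds; and 50 null-effect cohorts (n = 20/group, a size at which the
  t-based CI is already in its asymptotic regime) requiring ~95% CI coverage
  of zero. The large-study extraction path skips curvature/fractal features
  and the meshing of periventricular lesions (whose class is already decided
  by distance alone); these shortcuts change no reported quantity.

Slice thickness matters for shape recovery: with isotropic 1 mm voxels the
Spearman correlation between measured eccentricity and the generator's
intended elongation exceeds 0.8, while at 3 mm slices quantization noise
attenuates it (asserted above the weaker bound of 0.6) — the same accuracy
limitation thick-slice 2D FLAIR imposes on shape measurement in practice,
and the reason the correlation invariant is asserted on an isotropic cohort
with the anisotropic value tracked separately.

One further numerical subtlety is worth knowing: digital spheres are not
rotation-invariant objects. A sphere whose center coincides with a voxel
center has lattice-coherent staircase corners that measurably inflate the
caliper diameter and hence the eccentricity, while generic sub-voxel centers
do not; phantom checks therefore place sphere centers between voxels, the
generic configuration.

## Limitations

* Shape features below ~10 voxels are dominated by discretization; the
  5-voxel filter is a floor, not a guarantee of precision.
* Curvedness is reported in 1/voxel units and is not comparable across
  protocols with different voxel sizes.
* The KS normality p-values use estimated parameters and are
  anti-conservative.
* Registration to atlas space is an input contract: masks must already be
  on (or affinely mappable to) the atlas grid; no registration is performed.
* The caliper reduction for meshes beyond 2000 vertices is approximate at
  the ~0.2% level; exactness below that size is tested, not assumed, above.
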