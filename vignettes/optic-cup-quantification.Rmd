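---
title: "Quantifying optic cup, fissure and stalk morphogenesis with opticmorph"
author: "opticmorph authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying optic cup, fissure and stalk morphogenesis with opticmorph}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opticmorph)
```

## The measurement problem

During zebrafish optic cup morphogenesis (roughly 12--24 hours
post-fertilization), the optic vesicle folds into a cup, the optic stalk
narrows, and a transient ventral cleft -- the optic fissure -- forms between
two closely apposed tissue margins. Studying how these structures form, and
how they fail in coloboma models, relies on a battery of quantitative
measurements taken from 4D confocal imaging: how many nuclei are in a tissue
region, what fraction of them carries a photoconverted fate-mapping label,
how fast individual tracked cells move and how far they travel, how elongated
and how oriented single cells are, how large the fissure opening angle is,
what fraction of the vesicle an expression domain occupies, and how tissue
volumes compare between genotypes.

`opticmorph` implements that quantification layer as a tested, reusable
package. It does not segment, track, or render: interactive steps (drawing
cell outlines, clicking nuclei through time, orienting embryos for a
standard view) stay in the tools built for them, and this package consumes
their outputs -- image stacks, masks, centroid tables -- and produces
numbers. Every measurement can also be exercised on synthetic inputs with
planted ground truth, which is how the test suite validates the pipeline
end to end.

## The nucleus counting algorithm

The core of the package is a 3D nucleus detector for confocal z-stacks of
nuclear-localized fluorophores. The algorithm assumes one intensity peak per
nucleus and consists of four steps, exposed as `rescale_hi_lo()`,
`smooth_anisotropic()` and `find_nuclei()`:

1. **Hi-Lo linear rescaling.** Gray values are linearly mapped so the
   background level sits at 0 and a chosen ceiling sits one gray level below
   saturation (254 for 8-bit data), with clipping at both ends and floor
   rounding. This standardizes exposure differences between datasets.

2. **Anisotropic Gaussian smoothing.** Confocal stacks are anisotropic: the
   in-plane pixel size `dx` (about 0.7 µm at the 40x magnification this
   workflow targets) is much finer than the z-step `dz` (2.1 µm). The stack
   is low-pass filtered with a separable Gaussian whose z standard
   deviation, in voxel units, is `sigma_z = sigma_xy * (dx / dz)` -- i.e.
   the filter is isotropic in physical space. `sigma_xy` is specified in
   xy-voxel units (a micrometre option converts through `dx`). Boundary
   handling is symmetric reflection and the kernel is normalized (truncated
   at 4 sigma), so constants are fixed points and total intensity is
   conserved to well within 0.1% for interior-dominated images.

3. **Noise threshold `L`.** Voxels of the *smoothed* stack below `L` are
   set to zero. Whether the original workflow thresholded before or after
   filtering is not documented; thresholding after keeps the filter linear
   in the raw data and is the order fixed here (the two differ only near
   the noise floor).

4. **Extended maxima at height `h`.** Nuclei are the regional maxima of the
   result that survive suppression of all maxima whose *dynamic* -- their
   height above the highest saddle connecting them to higher terrain -- is
   below `h`. This is the classical extended-maxima (h-maxima) transform:
   grayscale geodesic reconstruction of `image - h` under `image`, followed
   by regional-maxima extraction (`grey_reconstruct()`,
   `extended_maxima()`). Maxima separated by saddles shallower than `h`
   merge into one detection, which is exactly the behavior wanted for
   double-lobed or unevenly stained nuclei. Connected plateaus are one
   region regardless of size (no peak splitting); the component
   connectivity defaults to 26 (the full 3D neighborhood), which merges
   diagonal plateau contacts and avoids double counting. Each component's
   centroid is the unweighted mean of its voxel positions, converted to
   micrometres; region centroids (not intensity-weighted ones) match the
   algorithm's description.

Two implementation details are worth documenting. First, after
thresholding, the background is a large zero plateau; the reconstruction
marker is therefore clipped at the background floor (0), which changes
nothing above the floor but keeps geodesic propagation local (the
reconstruction otherwise spends most of its sweeps flooding the empty
background). Components whose reconstructed value does not rise strictly
above the floor are background-merged and never reported -- equivalently,
a detection must have peak at least `L` (> 0) and dynamic above `h`.
Second, the iterative reconstruction is exact (it runs to a fixed point,
not a sweep budget); the test suite proves both the reconstruction and the
maxima/component structure equal an independent level-set (threshold
decomposition) oracle on hundreds of random grids at connectivity 6 and 26.

### Choosing `sigma_xy`, `L` and `h`

There are no universal values: in the original workflow they are tuned
per dataset by overlaying detected centroids on intensity isosurfaces and
adjusting until they match, and this package deliberately treats them as
required configuration rather than guessing defaults. Guidance from the
synthetic experiments in the test suite: `sigma_xy` of roughly half the
nuclear radius in pixels suppresses intranuclear texture without merging
neighbors; `L` needs only to clear the *smoothed* background (smoothing
shrinks noise by an order of magnitude, so `L` ~ 20 of 255 is ample for
raw noise s.d. up to ~10); `h` should exceed the residual background
relief but stay below the post-smoothing blob height (~half the smoothed
peak works well). With blobs of sigma 2 µm, amplitude 200, noise s.d. up
to 10 and separations above 12 µm, `sigma_xy = 2` voxels, `L = 20`,
`h = 30` recover 100% of planted nuclei with centroid RMSE below 0.1 µm
in plane.

## Fate-map fractions

Photoconversion fate mapping converts every nucleus in a region from green
to red fluorescence at an early stage; cells that move into the region
later remain green. The headline statistic is the proportion of green
nuclei among all nuclei in the optic cup. `marked_fraction()` runs the
detector independently per channel, restricts counts to an ROI mask, and
assembles `fraction = n_green / n_total`. How the original analysis
constructed the total is not recorded; the package default is
`n_total = n_green + n_red`, with partially converted, double-positive
nuclei (a green centroid within one nuclear radius -- default 3 µm,
configurable -- of a red centroid) counted once. A dedicated all-nuclei
counterstain channel can override this via the `total` argument. An ROI
with no detected nuclei yields a flagged undefined result rather than a
silent `NaN`.

## Trajectory kinematics and tracking QC

Manual 4D tracking produces per-cell centroid tables sampled at a fixed
interval (2.75 min between z-stacks in the cell-tracking datasets this
targets). `track_metrics()` reports the three standard per-cell metrics:

* **path length** -- the summed 3D inter-sample step lengths;
* **net displacement** -- the 3D straight-line distance from first to last
  position;
* **average speed** -- path length over elapsed time. The alternative
  reading (mean of framewise speeds) is numerically identical under
  uniform sampling, which the `trajectory()` constructor enforces: tracks
  with gaps are rejected rather than interpolated, since manual tracking
  is gap-free by construction.

Net displacement can never exceed path length; processive motion has the
two nearly equal, while fast-but-wandering cells (the mutant phenotype
this framework was built to detect) show inflated path length at unchanged
displacement. `overlap_ok()` implements the tracking acceptance rule of at
least 50% nuclear pixel overlap between consecutive time points; the
overlap fraction is normalized by the smaller mask, the permissive choice
for a manual-tracking QC, and the threshold is configurable.
`group_summary()` reports mean and sample (n-1) s.d. per group; published
"±" values do not state s.d. vs s.e.m., so the package always reports
s.d. and labels it as such.

## Morphometry

* **Roundness** (`roundness()`) is the Fiji/ImageJ shape descriptor
  `4 * Area / (pi * major_axis^2)` with the major axis from a second-order
  moment ellipse fit (a solid ellipse with semi-axes a, b has central
  second moments a²/4, b²/4). A circle scores 1.0, a needle approaches 0,
  and for an exact ellipse the descriptor equals minor/major. No
  discrete-pixel variance correction is applied; for the cell sizes this
  is used at (tens of pixels across) the discretization error is within
  the ±0.02 the tests enforce, and it vanishes with resolution.
* **Elongation angle** (`elongation_angle()`) is the axial angle between
  the fitted major axis and the embryo's anterior-posterior axis, folded
  into [-90°, 90°). Folding makes AP-aligned cells cluster near 0 so
  variance comparisons between genotypes are well-posed; a circular
  (directional-statistics) variance would be an alternative, but the
  folded-linear convention matches how the angles are measured and
  reported in practice. Angles are measured in image coordinates
  (positive toward +y); near-circular regions (roundness ≥ 0.95) have no
  stable axis and are flagged.
* **Fissure opening angle** (`fissure_angle()`) is the interior angle at a
  user-supplied vertex (the lens center) between rays through two points
  on the fissure margins, on a pre-oriented lateral view. The package does
  not locate the lens automatically.
* **Extent fractions** (`ap_extent_fraction()`,
  `reporter_midpoint_fraction()`) are interval ratios along the AP axis.
* **Quarter intensity ratio** (`quarter_intensity_ratio()`) reproduces the
  rectangular-ROI profile measurement: a 44-pixel-wide rectangle spanning
  the AP length of a vertically oriented vesicle, per-row means across the
  width, and the anterior quarter's mean over the posterior quarter's.
  For profile lengths not divisible by four, the outer quarters take
  `floor(n/4)` rows each (they drive the statistic and must be equal) and
  remainder rows go to the middle. The input must already be rotated to
  vertical, as in the source workflow.
* **Label volumes** (`label_volumes()`) converts labeled segmentation
  volumes to µm³ via voxel count × dx²·dz and reports each label's share
  of the total labeled volume (e.g. stalk / (cup + stalk)).

## Statistics

The comparisons used throughout this kind of study are deliberately plain:
unpaired Student's t (pooled variance) or Welch's t where variances
differ, the two-sided F test for comparing variances (the orientation-angle
phenotype is a variance difference, not a mean shift), Fisher's exact test
for 2x2 contingency outcomes (stalk vs cup by condition), and box plots.
The package wraps the reference implementations in base R behind a fixed
set of conventions: all p values two-sided; Fisher's two-sided p by the
probability-mass rule; box-plot hinges are *type-7* quartiles (the ggplot2
convention, not Tukey's `fivenum` hinges) with whiskers at the most
extreme attained values within 1.5 IQR of the hinges. Degenerate inputs
(zero variances, zero margins) return flagged results instead of errors
where a convention exists. `contingency_fraction()` and
`normalize_penetrance()` fix the display arithmetic: percentages to one
decimal with half-up rounding, and phenotype penetrance normalized to the
vehicle control (100 = no change).

No multiple-testing correction is applied anywhere, matching the source
analyses.

## The synthetic-data generator

The generator exists so that every downstream operation can be tested
against known truth:

* `make_nuclei_volume()` renders nuclei as isotropic 3D Gaussian intensity
  blobs sampled on the anisotropic voxel grid, plus additive zero-mean
  Gaussian noise, rounded and clipped to 8-bit. Defaults mirror the
  confocal geometry (spacing 0.692 x 2.1 µm; the conventional full frame
  is 512 x 512 x 60, though tests use smaller crops). Blob sigma defaults
  to 2 µm, making nuclei ~6-12 px across in xy -- a fixture choice
  consistent with 40x imaging of packed neuroepithelial nuclei, not a
  measured value. Channels render independently (no bleed-through),
  matching the separability assumption of the fate-map analysis.
* `sample_nucleus_field()` places centers by rejection sampling at a
  minimum separation (default 6 sigma, where blobs no longer interact)
  with a border margin.
* `make_ellipse_mask()` rasterizes rotated filled ellipses and records
  exact truth (roundness = minor/major, axial angle).
* `make_trajectory()` samples waypoint polylines at uniform Δt
  (default 2.75 min), allocating whole sampling intervals to segments so
  waypoints are always sampled and the noiseless sampled path equals the
  polyline length exactly; positional jitter is added on top.
* `make_labeled_volume()` builds disjoint labeled voxel sets with exact
  volume truth.

All generators are seeded and bit-reproducible, and restore the caller's
RNG state.

What the generator does *not* emulate -- and hence what passing tests do
not show -- matters: there is no optical point-spread function, no
depth-dependent attenuation, no autofluorescence structure, no nuclear
shape variation or mitotic figures, and no cell crowding below the
separation limit. Recovery results on synthetic volumes certify the
algorithmic chain (given blob-like, separated signals, the counts and
centroids are right), not detector performance on arbitrary real tissue;
on real data the parameters still need the visual tuning pass described
above.

## Numerical choices and degenerate inputs

* Coordinates are 0-based pixel centers; in-memory arrays are indexed
  `[x, y, z]`, TIFF planes on disk are row-major `[y, x]` in z-major
  order.
* Hi-Lo rescaling floors to integer gray values; the ceiling maps to
  `2^bit - 2` ("just below" saturation).
* Gaussian kernels truncate at 4 sigma; reflection boundaries.
* An all-background stack yields an empty centroid set (not an error);
  `h` at or above the dynamic range yields an empty set with a warning.
* Plateau ties: a connected equal-valued plateau is one maxima region.
* Ellipse fits reject collinear regions; masks touching the image border
  are rejected at generation time.
* Tests and simulations use fixed seeds; problem sizes (e.g. 200 random
  oracle grids, volumes of 60-150 nuclei at 160-220 px frames, 10,000
  null t replicates) were chosen to make the suite decisive at desk
  scale.

## Command-line use

For batch work, `inst/cli/opticmorph` exposes the common entry points as
a shell tool (`count`, `simulate-volume`, `trackstats`); the remaining
operations are one-liners in R and are used that way.
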