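---
title: "Quantifying feto-placental vascular density across scales"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying feto-placental vascular density across scales}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(placvasc)
```

## The measurement problem

A term human placenta perfused through the umbilical artery with a
radio-opaque casting agent can be imaged whole by micro-CT (isotropic
voxels of 116.5 um, resolving chorionic and stem vessels), as excised
tissue blocks (13.5 um voxels, resolving the villous tree down to but not
including terminal capillaries), and as H&E histological sections (all
vessel lumens, but only in 2D cross-section). The scientific question the
package serves is whether villous vascular density varies systematically
with tissue location between the umbilical cord insertion and the
placental edge, or is merely heterogeneous. That requires three things:
segmenting the vessel signal at each scale, expressing location in a
cord-centred normalised coordinate, and rank-based statistics that do not
assume normality.

`placvasc` implements that full chain, together with 3D and 2D phantom
generators whose ground truth is known voxel-by-voxel. All validation in
the package is against phantoms: the real placentas behind the published
measurements are not publicly deposited, so the tests demonstrate
correctness of the computations, not reproduction of any specific
specimen.

## Whole-placenta track

**Segmentation.** Both CT scales use greyscale-histogram thresholds: the
tissue threshold is the midpoint between the air and tissue peaks, the
vessel (Microfil) threshold the midpoint between the tissue and contrast
peaks. Peak finding is automated: the histogram (bin width at most
1/512 of the range, never below one intensity unit) is smoothed with a
moving average of width 1/64 of the intensity range; local maxima are
ranked by topographic prominence and selected greedily subject to a
minimum separation of four smoothing widths — without the separation
rule, sampling wiggles on the flank of a large mode can outrank the small
contrast mode, which is two orders of magnitude lower than the air peak.
Each selected peak is refined to the raw-count maximum within one
smoothing window, taking the lowest intensity on ties. Fewer than three
separable peaks is a hard error; `threshold_pair()` accepts manual values
for that case.

**Chunked processing.** Whole-placenta stacks are divided into a 10 x 10
in-plane grid of labelled 3D chunks that recombine bit-exactly
(`split_chunks()` / `merge_chunks()`); non-divisible extents are padded
with air at the high edge and cropped on merge. Chunks carry an optional
halo (default 7 voxels, one more than the radius filter below) so local
morphology agrees with whole-volume processing; per-region density needs
no halo at all and is verified chunk-vs-whole to exact equality.

**Geometry.** Location is normalised per direction: rays at 1 degree
spacing from the user-supplied cord-insertion point (the package has no
GUI; the coordinate comes from configuration) to the mask edge, measured
on a maximum-intensity projection of the stack. Each in-mask pixel is
assigned to its nearest angular sector; the sector's edge distance is the
radial distance of the outermost in-mask pixel within the sector and its
two neighbours, and the pixel's normalised distance is
`100 * r / edge(sector)`, 0 at the cord and 100 at the edge. The
one-sector window is a numerical necessity: near the axis directions a
1-degree arc at the rim subtends less than one pixel, so some sectors
contain no rim pixel at all and their unwindowed edge would be biased
short by more than a pixel. Where a mask boundary is crossed more than
once along a direction, the outermost crossing defines the edge, since
the quantity of interest is the distance to the placental edge. On a
rasterised disc of radius 50 the map deviates from the analytic
`100 r / R` by at most 1.9 units (about one pixel), and scaling the mask
2x changes values by less than one pixel at the original scale.

**Skeletonisation and radius.** The vessel mask is reduced to a
one-voxel centreline by distance-ordered homotopic thinning: foreground
voxels are visited in increasing order of their Euclidean distance to the
background (exact distance transform, computed by a separable
lower-envelope algorithm in C++) and deleted when deletion preserves
digital topology — 26-connectivity for vessels, 6 for background, decided
by an explicit simple-point test on the 3 x 3 x 3 neighbourhood — and the
voxel is not a curve endpoint. Distance ordering keeps the curve centred;
sequential deletion with re-checking makes the result deterministic and
idempotent. On an axis-aligned cylinder of radius 4 and length 60 the
skeleton is the exact axis over its interior, with ends receding about
2 voxels into each cap and wandering at most the local radius off-axis at
the very tips; radius estimates therefore use the median, and taper
checks exclude one radius length at each end. The per-voxel radius is the
distance transform of the mask evaluated on the centreline — the distance
from the midline to the thresholded vessel boundary. On digital cylinders
of radius 2–8 the median error is below 0.25 voxels.

**Large-vessel exclusion.** Vessels with local radius above 6 voxels
(about 700 um at the whole-placenta scale) are removed before density
analysis, since they are predominantly chorionic and stem vessels rather
than the villous tree of interest. Each mask voxel inherits the radius of
its nearest centreline voxel (nearest-seed transform, same C++ pass
structure as the distance transform); inheritance is voxel-wise, so a
vessel that tapers through the threshold is removed only where it is
thick. Residual voxels at cylinder end caps (where the centreline radius
dips) amount to under 5% on a radius-8 cylinder of realistic length.

**Density.** Vascular density of any region is vessel voxels over tissue
voxels (vessels are a subset of tissue by construction of the
thresholds), expressed in percent; regions without tissue are flagged
`NA`, never zero-filled. The radial profile aggregates voxels into 100
half-open normalised-distance bins (bin 99 includes 100); its
voxel-weighted mean equals the global density to machine precision, and
per-chunk maps use the same counts as whole-volume processing exactly.

## Block and histology tracks

**Block density.** For a tissue-block volume the region of interest is
the basal third of the tissue extent along z — the villous territory —
computed from the bounding slices of the tissue mask, a deterministic
surrogate for a manually drawn region. Density is vessel volume over
tissue-plus-vessel volume in the ROI.

**Histology classification.** Micrograph pixels are assigned to three
classes: perfused lumen plus background (the casting agent shrinks during
processing, so a perfused lumen is a bright contrast core inside a pale
rim, and the class deliberately includes the white background), unperfused
lumen (red cells), and villous tissue. The published workflow used an
interactively trained texture classifier whose model is not recoverable;
the package substitutes a deterministic nearest-prototype colour
classifier, with up to three k-means colour prototypes per class (fixed
seed, Lloyd iterations) trained on two fixed-seed phantom micrographs.
Multiple prototypes per class matter: the perfused-plus-background class
is colour-multimodal, and its mean colour lies closer to villous pink
than the contrast core does, so a single-centroid classifier mislabels
every core. Pre-made label images can be supplied directly, which keeps
the downstream arithmetic testable independently of classification.

**Particle analysis.** Connected components of a class mask
(8-connectivity) are measured in physical units and filtered to area
60–1,000,000 um^2 and circularity 0.20–1.00. Circularity is
`4 pi A / P^2`, capped at 1; the perimeter is Kulpa's weighted
boundary-step estimator (`0.9481 * (even steps + sqrt(2) * odd steps)`
along the Moore-traced outer boundary), which is close to unbiased for
smooth convex shapes — a digital circle of radius 50 px measures within
0.5% of `2 pi r`. Single-pixel components take the unit-square perimeter.
The area cap is what removes the background component of the
perfused-plus-background class: at a realistic x100 field
(about 1.38 x 1.08 mm) the background exceeds 1,000,000 um^2. Note the
corollary that this filter logic presumes fields of at least that area.

**Fill, density and inclusion.** Vascular fill above an area cutoff is
the perfused share of total lumen area among vessels larger than the
cutoff; 10,000 um^2 corresponds to vessels resolvable at whole-placenta
scale (computed over all micrographs of a block) and 200 um^2 to the
block-imaging scale (basal micrographs only, matching the imaged
territory). Histological vascular density is lumen area over villous-plus-
lumen area, mirroring the volumetric definition. Blocks with fill below
75% at the 200 um^2 cutoff are excluded from density analysis — the
published criterion, applied non-strictly, so a block at exactly 75% is
kept. With no qualifying vessel the fill is undefined (`NA`) and the
block is excluded.

**Statistics.** Density-location association uses Spearman rank
correlation (midranks for ties, two-sided p from the t approximation);
between-placenta comparison uses the tie-corrected Kruskal–Wallis H test
with Dunn's pairwise z tests and Bonferroni correction over all unordered
pairs. Summaries report the sample (n−1) SD and linear-interpolation
quantiles. Significance is fixed at 0.05. Both rank statistics are tested
against brute-force rank formulas to 1e-12, the Kruskal–Wallis type-I
error is calibrated to 5% +/- 1.5 points under a simulated null, and
Spearman p-values are checked for approximate uniformity.

## What the phantoms emulate — and what they do not

`generate_volume_phantom()` renders a disc of tissue (slices parallel to
the chorionic plate, z increasing towards the basal plate) with a
three-mode greyscale histogram, and branching vessel trees descending
from roots on the chorionic face: recursive binary branching with a
per-generation radius taper, random branch angles of 25–50 degrees, and
segment capsules rasterised into the voxel grid. Unperfused terminal
segments are rendered at tissue intensity — physically, a lumen the
casting agent never reached is invisible to thresholding. Noise is
additive Gaussian, clipped to the 16-bit range, with SD defaulting to 10%
of the tissue-air gap, small enough that the histogram modes stay
separable (and the default intensities keep the air mode well away from
the clip at zero, which would otherwise manufacture a spurious fourth
mode). Tree roots are sampled uniformly per unit area on a disc enlarged
by half the disc thickness — the expected lateral tree extent — so that
the volume lost where edge-rooted trees are clipped by the tissue
boundary is replenished by trees rooted just outside; without this
"plus-sampling" the periphery is systematically depleted and the null
profile acquires an artificial trend. A `density_gradient` parameter
reweights root placement linearly in radius; `target_density` adds trees
until a requested global vessel fraction is reached. Defaults
(160 x 160 x 40 voxels, disc radius 72, thickness 32, 48 trees of root
radius 1.8 voxels, 3 generations, taper 0.8) give a villous-scale density
of a few percent; these sizes are scaled-down study conditions chosen so
that a full analysis runs in seconds, and they are stated here as the
package's validation conditions.

Ground truth carries the tissue and perfused-vessel masks, centreline
samples with true radii, the analytic normalised distance of every
in-plane position (exact disc geometry, valid for off-centre cord points
too), and per-bin density by brute-force voxel counting.

The phantoms do not emulate X-ray physics (beam hardening, ring
artefacts), partial-volume blur at vessel boundaries, anatomically
realistic branching statistics (which the literature does not quantify
for human placenta at these scales), non-disc placental shapes, or
spatially varying perfusion quality. A passing test suite therefore
demonstrates that the measurement chain is correct on data obeying its
idealised assumptions, not that segmentation thresholds or the classifier
would transfer unchanged to scanner data.

Two statistical properties of tree phantoms deserve emphasis because they
shaped the validation design. First, vessels are spatial clumps: one tree
spans roughly 20 of the 100 radial bins, so a single phantom's profile
has only a handful of effective degrees of freedom and its rank
correlation with bin index is noisy (SD about 0.4) even under perfect
homogeneity; no-trend checks therefore average the rank correlation over
replicate phantoms and exclude the innermost annuli, which hold a handful
of voxel columns and are skew-distributed. For the same reason the
estimated profile is compared bin-by-bin against ground truth counted in
the same measured geometry (isolating segmentation and aggregation, at
0.5 percentage points), while the geometry itself is validated separately
against analytic discs and ellipses — against analytically binned truth,
sub-pixel edge discretisation flips whole vessel clumps across the
0.72-voxel-wide bin boundaries and any correct implementation shows
percentage-point-scale disagreement. Second, block surveys on a single
phantom are spatially correlated; the null-pattern experiment therefore
mirrors the published design — ten placenta phantoms with eight
non-overlapping blocks each per run — under which the location
correlation behaves like a clean null.

`generate_micrograph_phantom()` rasterises villous regions, perfused
lumens (core plus rim) and unperfused lumens as non-overlapping ellipses
with per-ellipse analytic areas; lumens must lie inside villous regions,
both for biology and because a lumen on the background would merge with
its own class. The default field matches a x100 photomicrograph so the
particle filters behave as published (see above).

## Degenerate inputs and tie-breaks

Empty vessel masks skeletonise to empty skeletons (not an error); a
single voxel is its own skeleton with radius at most 1. Histogram
plateaus resolve to the lowest intensity; priority ties in thinning
resolve in insertion order; nearest-seed ties resolve by scan order — all
deterministic. Volumes with constant intensity, bimodal histograms, cord
points outside the mask, masks whose edge touches the cord, blocks with
fewer than three tissue slices, empty manifests and missing scale
metadata all raise typed errors (`placvasc_config_error` /
`placvasc_data_error`; the command-line wrapper maps them to exit codes
2 and 3).

## Known limitations

Thresholding is global per volume (the published workflow set thresholds
per placenta; per-block histograms are accepted by passing a block's own
volume). The skeleton is computed on the whole volume rather than
chunk-wise: thinning is a global operation and the validated volume sizes
fit comfortably in memory; chunked processing is exact for density maps,
which need no halo. Radius-based exclusion inherits centreline radii
voxel-wise, so the boundary between a stem vessel and its daughter is cut
at the voxel, not the branch, level. The pixel classifier is a colour
model: it is deterministic and exact on phantom renderings but makes no
claim to robustness against staining variation in real H&E material.

## A worked example

```{r example, eval = FALSE}
library(placvasc)

ph <- generate_volume_phantom(phantom_spec_3d(seed = 1,
                                              target_density = 0.05))
th <- find_thresholds(ph$volume)
seg <- segment_volume(ph$volume, th)
skel <- measure_radius(skeletonise(seg$vessel_mask), seg$vessel_mask,
                       ph$volume$voxel_size_um)
vessels <- exclude_large_vessels(seg$vessel_mask, skel, 6)
geom <- compute_distance_map(
  max_intensity_projection(ph$volume) >= th$tissue_threshold,
  ph$truth$cord_point)
profile <- radial_profile(vessels, seg$tissue_mask, geom)

global_density(vessels, seg$tissue_mask)  # ~ the 5% ground truth
plot(profile)
```
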