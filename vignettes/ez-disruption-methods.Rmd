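---
title: "Methods: automatic 3D detection of ellipsoid-zone disruption in SD-OCT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automatic 3D detection of ellipsoid-zone disruption in SD-OCT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model behind `ezdetect`, the assumptions it
makes, every tunable parameter that matters, what the synthetic phantoms do
and do not emulate, and the numerical and design choices taken where the
problem was genuinely open. It states no empirical result beyond what the
package's test suite and `scripts/acceptance.R` themselves compute.

## The problem and the pipeline

Spectral-domain OCT resolves the retina into layers; the ellipsoid zone (EZ)
is the second hyper-reflective outer-retinal band, and focal EZ dropout marks
photoreceptor damage. The package classifies every voxel of the EZ slab of a
macular volume as disrupted or intact and reports the physical disruption
volume. The pipeline is: per-B-scan bilateral denoising; segmentation of 11
retinal surfaces; thin-plate-spline smoothing; flattening to the RPE floor;
extraction of the EZ slab (between surfaces 7 and 8) as the volume of
interest (VOI); a 57-feature descriptor per VOI voxel reduced to 10 PCA
scores; under-sampling-balanced discrete AdaBoost with leave-one-out
cross-validation; vessel-silhouette and morphological post-processing; and
confusion/volume/agreement statistics.

Coordinates are fixed as `(x, y, z)` = (lateral position within a B-scan,
B-scan index, axial depth increasing toward the choroid), 1-based as usual in
R. Surfaces are stored at sub-voxel precision; voxel membership between two
surfaces uses the half-open rule `z in [round(z_a), round(z_b))`, with a
degenerate column keeping the single voxel at `round(z_a)`. Flattening moves
each A-scan by an integer (no interpolation), so a second flattening is the
identity. Intensities are treated as unitless reals in their native range;
min–max normalization over the VOI happens once, at the feature stage.

## Denoising

Speckle in OCT is multiplicative, so each B-scan is filtered independently
with a bilateral filter: spatial Gaussian width `sigma_spatial` (default 3
px), range width `sigma_range` (default 10% of the slice's dynamic range).
The fast implementation is a bilateral grid: (intensity, weight) pairs are
splatted trilinearly into a space × space × range grid (cell sizes
`downsample_spatial` pixels and `downsample_range · sigma_range/4` intensity
units), the grid is blurred with separable Gaussians truncated at 4σ, and the
blurred ratio is read back by trilinear interpolation. With unit downsampling
factors this reproduces the direct double-loop bilateral sum to well under 2%
(checked against a brute-force oracle in the tests); the output is a convex
combination of slice intensities, so a slice's intensity range never widens.
The 4σ truncation matters: at 3σ the residual tail of the range kernel is
large enough to shift values by several percent when a pixel has no close
neighbours in intensity.

## Surface segmentation

Each surface maximises the sum over columns of a polarity-signed axial
forward-difference gradient, subject to a hard lateral smoothness bound
(`smoothness`, default 1 voxel per column — macular surfaces at ~12 µm
lateral sampling are much flatter than this) and per-layer min/max separation
bounds. Defaults for the separation bounds are half and twice the nominal
layer thicknesses of the package's anatomical layer model. The optimum for
one B-scan is found exactly by dynamic programming over columns; the
multi-resolution mode (`levels`, default 2) solves a 2×-downsampled problem
first and restricts the fine search to a band around the coarse solution,
with bound mapping that is conservative (a coarse cell must lie wholly inside
the fine band) wherever the band is wide enough. The DP is verified against
exhaustive path enumeration on tiny instances.

Search order is the load-bearing design choice. Two anchors are found first:
surface 1 (the inner limiting membrane — its cost penalises mean intensity
*above*, since only the vitreous is uniformly dark) and surface 11 (the RPE
bottom — penalising mean intensity *below*, the choroid; weight
`anchor_penalty`, default 2). The outer surfaces 10, 9, 8, 7 are then found
*bottom-up*, each within one layer's separation band of the surface below.
This keeps every band local: the EZ top (surface 7) is normally the strongest
dark-to-bright boundary, but inside a disrupted patch its gradient collapses,
and a top-down search with wide bands happily snaps to the outer-segment/RPE
boundary instead. Searching upward from the (disruption-immune) RPE keeps
exactly one candidate boundary of the right polarity in each band, so the EZ
boundaries are recovered even across large dark lesions. Inner surfaces 2–6
follow top-down between surfaces 1 and 7. Degenerate bands (conflicting
constraints) collapse to their midpoint, and ties in the DP prefer the
flattest path, so featureless stretches are bridged level rather than by
drift.

Thin-plate-spline smoothing (basis dimension `k = 64`, fixed regularization
0.1, fit grid subsampled to ~1200 points) removes residual column noise; TPS
reproduces affine surfaces exactly and tends to the best-fit plane as the
regularization grows. The fit is robust by default (`robust_iter = 2`): a
stiff detection pass flags columns whose residual exceeds
`max(2, 3·MAD)` voxels and the final fit interpolates across them from
reliable columns. The stiff detection pass is what prevents self-masking — a
flexible fit follows a lesion-sized excursion well enough to hide it from its
own residuals.

## Features, selection, classification

For each VOI voxel the descriptor is, in fixed column order: normalized
intensity (min–max over the volume's VOI voxels); 5×5×5 block mean and
population standard deviation (blocks cropped at volume edges); the mean
absolute intensity difference over 13 directions at steps 1 and 2
(out-of-volume neighbours clamped; `mean` aggregation by default, `max`/`sum`
available); and GLCM contrast, correlation, energy and homogeneity over the
same 13 directions (57 features in total). The 13 directions are the distinct
half-axes of the 26-neighbourhood, parameterised by an azimuth in the X–Y
plane and an elevation from the Z axis; only 12 angle pairs are conventional
to list, and the set is completed by the remaining half-axis `(1, −1, 1)`.
GLCMs are built per 5×5×5 block at offset one grid step, accumulated
symmetrically, normalized to probabilities, with out-of-block pairs skipped
and a degenerate (pairless) matrix flagged and given all-zero properties;
correlation of a zero-variance marginal is defined as 0. Intensities are
quantized for the GLCM into `n_levels = 8` equal bins over the VOI's
normalized range (configurable); the descriptor is computed on normalized
intensities throughout so the texture features are invariant to affine
intensity rescaling of the acquisition. The hot loop is compiled (Rcpp); the
exported scalar R operations are the reference implementations and the test
suite checks the compiled matrix against them to 1e-10.

The 57 features are standardized (zero-variance columns pass through as
zeros) and reduced to the first 10 principal components; a warning is raised
if they explain less than 90% of the variance. Training sets are balanced by
keeping all disrupted voxels and drawing an equal number of intact ones
without replacement (single draw per fold, pooled across training eyes —
per-eye balancing is available via the exported function). The classifier is
classic discrete AdaBoost over depth-1 decision stumps on the 10 scores:
`T = 100` rounds by default, stump thresholds at midpoints of sorted unique
values, `α = ½·ln((1−ε)/ε)` with ε clamped to `[1e-10, 1−1e-10]`, early stop
at ε ≥ 0.5 or ε ≤ 1e-10. Stumps on 10 standardized scores make the weak
learner family simple, fast and scale-free; ties (zero margin) classify as
intact, the conservative choice for a detector. The leave-one-out driver
refits the PCA inside every training fold — scores fitted on all eyes would
leak the held-out eye's distribution into training.

## Post-processing

Vessel shadows darken everything below the inner retina and mimic disruption
in the EZ. The EZ→RPE slab (surfaces 8–11) is projected en face by averaging
along z; per-pixel features (normalized intensity, 9×9 local mean and
standard deviation, maximum dark-line filter response over four orientations)
feed a KNN classifier (`k = 15`, majority vote) trained on seeded synthetic
projections with known vessel paths; components under 5 px are dropped. A
parameter-free fallback (threshold at 70% of the median) is available.

Detections are then filtered in three steps: components lying wholly inside
the radius-2-dilated vessel map are removed; morphological opening then
closing with a radius-5 disk on the en face footprint removes isolated
detections and fills isolated holes (each column's VOI voxels are set or
cleared together); finally, remaining detection columns that coincide with
the vessel map are cleared. Clearing vessel overlaps only *after* the size
filtering is deliberate: a vessel crossing a genuine lesion would otherwise
split its footprint into lobes thin enough for the opening to erase. The
end state is the same — no detection survives on a vessel column, no
isolated specks survive — but real lesions are not fragmented first. The
structuring element is 2D by design: the EZ slab is only ~3–4 voxels thick,
so a literal 3D ball of radius 5 would erase every possible detection; the
3D ball remains available via `element = "ball3d"` for isotropic masks.

## Evaluation

All confusion counts are restricted to the VOI, where classification is
defined: `SEN = 100·TP/(TP+FN)`, `SPE = 100·TN/(TN+FP)`,
`BAR = (SEN+SPE)/2`; a metric with a zero denominator (SEN on a normal eye)
is reported as `NA` rather than an error. Disruption volume is the voxel
count times the physical voxel volume, in mm³ at full precision. Cohort
summaries use the t-based 95% CI (at n = 15 the difference from the normal
quantile is negligible, but the t form is exact); correlation inference is
Pearson with Fisher-z CI; agreement uses Bland–Altman limits
`mean(d) ± 1.96·sd(d)`; the group comparison is a pooled-variance Student
t-test (Welch via a flag). The standard confusion-matrix definitions are
used throughout (false positives counted as false positives).

## The synthetic phantoms

`phantom_config()` defines the package's reference study conditions: a
128×32×128 volume at 11.72 × 93.75 × 3.50 µm (a 6×6 mm macular scan at
reduced sampling so a full-pipeline run takes minutes, not hours); ten layers
with distinct reflectivities and the EZ brightest; smooth tilt plus a foveal
dip fading to zero at the EZ; two planted disruption blobs of en face radius
8–14 voxels whose intensity drops to 30% of the EZ reflectivity; two vessel
paths of width 3 attenuating everything below the inner retina to 35%; and
mean-1 multiplicative gamma speckle with standard deviation 0.2, applied
last. Voxel membership uses the same half-open rounding rule as the VOI, so
a noise-free phantom's per-layer means equal the configured reflectivities
exactly. The blob sizes are chosen to reproduce trauma-scale disruption —
per-eye disrupted fractions of the EZ around 10–25%, inside the roughly
2–50% range of disruption-to-EZ volume ratios seen in real trauma eyes —
which makes the per-eye imbalance heavy-tailed across a cohort (normal eyes
are all-majority; far more extreme ratios are reachable by shrinking the
radii). The generator reports the realised imbalance and blob records, and
every phantom is a deterministic function of its seed.

What the phantoms do **not** emulate: wave-optics speckle correlation, motion
artefacts, signal roll-off with depth, pathology other than clean-edged EZ
dropout, vessel calibre variation, and the anisotropic point-spread function
of real devices. Passing the end-to-end tests therefore shows that the
pipeline's logic is correct and self-consistent under controlled conditions
with a known answer — not that clinical performance on device data would
match; on real scans the segmentation and the classifier face blur,
transitional lesion margins and grader subjectivity that the phantoms
deliberately exclude.

## Numerical choices and degenerate inputs

* Surfaces at sub-voxel precision; ordering re-enforced by minimal axial
  shifts (`pmax`) after smoothing; all positions clipped to `[1, nz]`.
* Constant VOI: normalized intensities all 0; GLCM energy/homogeneity 1,
  contrast 0, correlation 0.
* Empty VOI is an error; an empty projection band falls back to its top
  voxel and is flagged.
* `disruption_volume` keeps full floating-point precision (no rounding).
* NIfTI I/O round-trips doubles bit-for-bit; TIFF stores 32-bit samples
  (round trip exact to ~2.4e-10) and requires intensities in `[0, 1]`.
* Reported problem sizes: the reference cohort is 6 phantoms of 128×32×128
  voxels (4 trauma, 2 normal) with ~14,000 EZ voxels per eye; the package's
  own checks run the whole pipeline twice at these sizes in a few minutes on
  one CPU.

## Known limitations

* The surface search is per-B-scan dynamic programming with hard bounds, a
  simplified stand-in for full 3D graph-search segmentation; smoothness
  across B-scans comes only from the TPS stage.
* The bottom boundary of a disrupted EZ (surface 8 inside a lesion) is
  genuinely low-contrast; its position there is effectively interpolated by
  the flat-path tie-break and the TPS, not measured.
* The vessel detector is trained on synthetic projections; on device data it
  should be retrained or replaced (the adaptive threshold is a starting
  point).
* Pipeline reruns recompute every stage; no digest-keyed artifact cache is
  kept. Reruns are cheap at the package's problem sizes and byte-identical
  by seeding, which removes the main motivation for a cache and its
  invalidation risk; the config digest is still embedded in every output.
* Normal-only cohorts cannot train the supervised classifier; the pipeline
  falls back to a fixed low-intensity rule (normalized intensity < 0.25) so
  specificity is still measurable, and flags SEN/BAR as undefined.
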