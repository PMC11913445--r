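---
title: "Quantifying giant endosomal-lysosomal assemblies in 3D"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying giant endosomal-lysosomal assemblies in 3D}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elysar)
```

## The measurement problem

Mammalian oocytes concentrate their degradative machinery into giant
endosomal-lysosomal organellar assemblies (ELYSAs): spherical, ellipsoidal
or concatenated aggregates that can reach 7--10 µm in diameter, repositioning
from the cell interior toward the cortex as the oocyte matures from the
germinal-vesicle (GV) stage to metaphase II (MII), and dispersing again over
the 2-cell stages. Asking quantitative questions about these structures --
how many are there, how large, how far from the cell center, which marker
channels they share, how acidic they are -- requires reconstructing them as
3D objects from multi-channel confocal z-stacks of single cells.

`elysar` implements that workflow end to end: 3D object reconstruction
(background subtraction, thresholding, connected-component labeling),
equivalent-sphere morphometry, a radial "distal distance" statistic with
peripheral/medial zoning, object-based colocalization, ratiometric
acidification imaging, and per-cell group statistics. Because raw microscopy
of this kind is rarely redistributable, the package also ships a synthetic
confocal-scene generator with exact ground truth; every quantitative claim
the test suite makes is checked against that truth, against closed forms, or
against brute-force oracles.

## The reconstruction model

A cell is imaged as a z-stack with voxel sizes $(d_z, d_y, d_x)$ in µm; the
physical position of voxel $(k, j, i)$ is its center,
$((k-0.5)d_z,\,(j-0.5)d_y,\,(i-0.5)d_x)$. Reconstruction of one channel
proceeds as:

1. optional in-plane Gaussian blur (default $\sigma = 1$ px, the common
   slice-wise enhancement filter);
2. background estimation -- by default the mean of the per-region means of
   four rectangular "blank regions" outside the cell -- and subtraction,
   clamped at zero so Poisson-like data stay non-negative;
3. strict thresholding: a voxel is foreground iff its corrected intensity
   strictly exceeds the threshold. The threshold is per-run configuration
   (values around 600--1200 are typical for 16-bit-scale immunostaining
   stacks; the default is 1000, half the plateau intensity of the synthetic
   scenes, which is the FWHM criterion that recovers a blurred step edge at
   its true position). An automatic Otsu mode exists as a clearly labeled
   extension.
4. 3D connected-component labeling at 26-connectivity by default (the usual
   3D object-counting convention; 6 and 18 are available because the
   choice is a genuine degree of freedom);
5. per-object measurement: voxel count, volume $V$, integrated and mean
   intensity, and the *unweighted* geometric centroid of member voxel
   centers. "Geometric center" is taken literally rather than
   intensity-weighted; the two differ only for asymmetric intensity
   profiles, and the unweighted form is exactly testable;
6. size filtering, keeping volumes in $(V_{\min}, V_{\max}]$ (default
   $(0, 5000]$ µm³), which removes plasma-membrane sheets; an optional
   deterministic boundary-exclusion rule (drop objects whose centroid lies
   within a set distance of the cell-mask boundary) stands in for the manual
   erasing a human operator would do -- manual steps cannot live in a
   reproducible pipeline, so the automated surrogate defaults to off and is
   documented as such.

Cell geometry comes from the reference channel: the center plane is the
midpoint of the first and last z-planes carrying above-threshold signal, the
cell mask is the hole-filled largest bright region of that plane (Otsu on
the plane), and the 3D cell center combines the mask centroid with the
center-plane height. This relies on the diffuse cytosolic component of real
stainings; the synthetic generator therefore adds a cytosolic haze term,
without which no center could be found. If the center plane happens to carry
no bright region (possible only in sparse synthetic scenes without haze),
the mask falls back to the maximum projection.

## Morphometry and radial statistics

Sizes are reported as equivalent-sphere diameters, $d = (6V/\pi)^{1/3}$.
One fine bin partition (0.2, 0.4, 0.6, 0.8, 1, 2, ..., 10 µm) underlies all
size-class reporting; coarser verbal classes (0.2--0.8, 3--7, 9--10 µm, ...)
are sums of fine bins, so a single partition serves many views. Bins are
half-open $[lo, hi)$ with a closed last bin, making boundary diameters
deterministic; objects outside the edge range are counted separately, never
silently dropped.

The radial statistic is the *distal distance*: the Euclidean distance from
the 3D cell center to the object centroid **plus** the object's mean
centroid-to-surface distance. The additive term prevents a large cortical
assembly from being scored as medial merely because its centroid sits
inward. Surface voxels are member voxels with at least one face-adjacent
(6-neighborhood) non-member -- the standard digital surface, brute-force
checkable -- even though labeling itself may use 26-connectivity. All
distances are computed in physical µm with anisotropic voxel sizes.

Zoning is strict at both cutoffs: distal distance > 30 µm is peripheral,
< 25 µm is medial, and the 25--30 µm band is reported as intermediate
rather than discarded. Large-object zone counts restrict to equivalent
diameters strictly above 4 µm by default.

Object-based colocalization asks whether the geometric center of a
partner-channel object (segmented with the same machinery and its own
threshold) falls inside a reference-channel object: centers map to voxels by
floor division of physical coordinates, a coordinate exactly on a voxel edge
mapping to the higher index. A reference object with at least one partner
center inside is double-positive. The stricter center-to-center distance
variant was considered and rejected as the default because
center-inside-object is the standard object-based test and is insensitive
to the partner object's own size.

Ratio images divide the background-corrected mean projections of two acidity
channels (numerator/denominator, e.g. LysoTracker/LysoSensor). Each channel
gets its own blank-region background estimate, clamped at zero before
division. Pixels whose corrected denominator does not exceed a floor
(default: three standard deviations of the denominator's blank-region
pixels) are masked invalid instead of producing unstable or infinite
ratios; per-object statistics use valid pixels only and flag objects with
none. Ratios are computed on mean projections, matching how such images are
usually presented; a full-3D variant would only require replacing the
projection step.

## Group statistics

The analysis unit for between-stage comparisons is the per-cell summary
(one value per oocyte/embryo), not the individual object -- objects within
one cell are not independent. `compare_groups()` runs one-way ANOVA across
groups followed by Tukey's HSD (both via base R's `aov`/`TukeyHSD`), reports
mean ± SEM per group, and assigns a compact letter display by
insert-and-absorb: start with one letter set holding every group, split any
set that still joins a significantly different pair, absorb subset sets, and
letter the survivors. Groups sharing a letter are not significantly
different at the chosen level (0.05 by default). Degenerate input (all
values identical) is reported as no-difference with a note rather than an
error. On null data (two groups from one distribution, n = 10 per group) the
test suite checks that Tukey stays non-significant in at least 90% of 100
seeded replicates.

## What the synthetic generator emulates -- and what it does not

A scene is a ~75 µm spherical cell centered in the acquisition grid,
containing phantoms (spheres, ellipsoids, chains of overlapping spheres)
with per-channel mean photon counts. Rasterization includes a voxel iff its
center lies inside the analytic solid -- simple and brute-force checkable --
with partial-volume effects entering only through the PSF; a sub-voxel solid
that captures no voxel center digitizes to the single voxel containing its
center. Acquisition is modeled per channel as

$$\mathrm{Poisson}\big(\mathrm{blur}(\text{field}) + \text{background}\big)
  + \mathcal{N}(0, \sigma_{\text{read}}^2),$$

clamped at zero: a separable Gaussian PSF in physical units (converted to
per-axis voxel sigmas, so anisotropy is handled by division by voxel size),
Poisson photon noise, then additive Gaussian read noise. This
Poisson-plus-Gaussian chain is the standard confocal approximation; it is a
modeling choice, not a fitted noise model. Radially placed phantoms get a
direction drawn uniformly on the sphere, rejected until the phantom fits in
the cell and clears previously placed phantoms (largest phantoms are placed
first, since the reverse order can deadlock). A fixed seed makes the
rendered stack bit-identical across runs.

Stage presets emulate the qualitative regimes of oocyte maturation on the
81-plane / 1-µm grid at 0.35 × 0.35 µm pixels (256 × 256 × 81, chosen to
keep a desk-scale render in seconds): GV-like scenes carry 120 small
(0.2--0.8 µm) assemblies plus 8 large (4--5.5 µm) ones placed medially;
MII-like scenes carry 25 assemblies of 3--7 µm, the >4 µm ones placed so
their true distal distance exceeds 30 µm; 2-cell presets replace large
assemblies with 1--3 µm structures, the early stage adding one
chain-of-spheres phantom for the transient concatenated morphology at
division. LAMP1 marks every phantom; RAB5 and LC3 membership is drawn as an
exact 30% subset (rounded, sampled without replacement) so the programmed
rate is realized exactly and recovery can be tested at a fixed target.
Per-stage abundances are qualitative emulations -- plotted distributions in
the literature do not pin down absolute counts -- so the presets fix one
realistic choice rather than calibrate to any dataset. A separate
two-channel acidification preset (41 planes at 2 µm) programs per-structure
Tracker/Sensor ratios directly.

The generator deliberately omits spectral bleed-through, photobleaching,
depth-dependent PSF broadening, optical sectioning beyond a Gaussian PSF,
and motion. Passing tests therefore demonstrate that the *measurement*
chain is correct under a faithful-but-idealized acquisition model; they do
not certify performance on aberrated or low-SNR real data, where threshold
choice (the one manual step this workflow inherits) dominates.

## Numerical choices and degenerate inputs

* Strict `>` at the segmentation threshold and at both zone cutoffs;
  equality cases are tested explicitly.
* Labels are contiguous from 1 in raster-scan order of first-encountered
  voxels, making label order deterministic (and irrelevant: tests permute
  labels and require identical results).
* The blurred-edge bias of threshold segmentation is the dominant sizing
  error: at half-plateau threshold the recovered diameter of a d ≥ 3 µm
  sphere under a (1, 0.35, 0.35) µm PSF is within a few percent of its
  digitized truth; below ~2 µm (approaching the axial PSF) objects dim and
  shrink nonlinearly, which is why the recovery criteria restrict to the
  resolvable regime.
* Empty masks label to zero objects; empty tables bin to all-zero
  distributions; 0/0 stage-ratio bins are flagged undefined (positive/0 is
  infinite, unflagged); ratio images with no valid pixel carry a warning
  instead of crashing; a failing cell in a multi-cell run reports its id
  and stage and does not abort the others.
* TIFF stacks are stored as float32 scaled to [0, 1] with the scale factor
  and physical metadata in a JSON sidecar, because the available TIFF
  writer clamps out-of-range floats; round trips are exact to float32
  precision.

## Problem sizes used by the test and acceptance runs

The suite labels one hundred 20³ random volumes against a pure-R flood-fill
oracle at all three connectivities; digitized-sphere morphometry uses a 6-µm
sphere at 0.2-µm isotropic voxels (~14,000 voxels); detection/zoning
recovery, colocalization and determinism run on full-size preset scenes
(256 × 256 × 81, 25--71 phantoms); ratio recovery uses the 128 × 128 × 41
acidification preset; the null-ANOVA check uses 100 replicates of n = 10 per
group. These sizes make the whole suite run in a couple of minutes while
keeping every scene at the preset acquisition geometry.

## Known limitations

* The segmentation threshold remains a per-run choice, as in the manual
  workflow it automates; the Otsu mode is a convenience, not a validated
  replacement.
* Sub-resolution structures (0.2--0.8 µm) are generated and carried in
  ground truth but are not reliably detected at default settings -- as in
  the physical experiment, where they sit at the diffraction limit.
* Colocalization is asymmetric by design (partner centers in reference
  objects); swapping roles changes the question.
* The compact letter display is one of several valid CLDs when the
  significance relation is non-transitive; insert-and-absorb is used and
  letters are checked against the pairwise significance matrix, not against
  a unique reference rendering.
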