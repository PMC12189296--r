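---
title: "Random-walker ensemble segmentation and radiomic concordance: methods"
author: "rwensemble maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random-walker ensemble segmentation and radiomic concordance: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rwensemble)
```

## The problem

Radiomic biomarkers for lung adenocarcinoma are only as reliable as the
segmentation that produced them. This package implements a slice-wise
random-walker *ensemble* segmentation of lung nodules in CT stacks,
extracts 38 canonical radiomic features from the segmented region, and
quantifies how well those features agree with features extracted from
ground-truth masks, using tie-aware Spearman rank concordance. A
deterministic synthetic phantom generator supplies CT-like test cases of
the three canonical nodule classes — solid, juxta-vascular (attached to a
vessel) and juxta-pleural (attached to the chest wall) — with analytic
ground truth, so the whole pipeline can be exercised and validated
without any patient data.

## Random-walker segmentation

Each slice is treated as a 4-connected lattice graph whose edge weights
are Gaussian in the intensity difference of the adjacent pixels,

$$w_{ij} = \exp\!\big(-\beta\,(g_i - g_j)^2\big) + 10^{-10},$$

with intensities first normalized to $[0,1]$ via `autoWindow()`. The
windowing op defaults to robust percentile clipping at the 1st/99th
percentiles — the reproducible analog of an interactive auto-contrast
step — but the pipeline normalizes the *segmentation* input over the
full intensity range (`pLow = 0, pHigh = 100`): percentile clipping is
designed to discard rare extremes, and in nodule CT the structure of
interest is itself a rare extreme. When a nodule occupies less than the
top percentile of stack voxels, a 99th-percentile clip lands inside the
lung-noise distribution, the nodule saturates together with the noise
tail, and the walker loses the lung/nodule contrast entirely. Given one
foreground and one background seed pixel, the foreground probability at
every pixel is the harmonic function with Dirichlet boundary values 1 at
the foreground seed and 0 at the background seed — equivalently, the
probability that a random walk with transitions proportional to edge
weights reaches the foreground seed first. The solution is obtained by a
direct sparse factorization of the unseeded block of the graph Laplacian
(conjugate gradients above $10^5$ unknowns, residual tolerance `1e-8`).
The weight floor of $10^{-10}$ keeps the system nonsingular on constant
regions; it is orders of magnitude below any informative weight.

Parameters, with units and defaults:

* `beta = 130` (dimensionless, for intensities in $[0,1]$): sharpness of
  the intensity barrier. The conventional order of magnitude for this
  formulation; higher values harden boundaries, lower values let the
  walker diffuse across faint edges.
* `threshold = 0.5`: the probability level at which a pixel is called
  foreground, with the boundary value counted as foreground. 0.5 is the
  majority label of the two-label problem.
* Connectivity is fixed at 4; the problem is solved slice by slice
  (two-label only — the background probability is the complement).

## The ensemble driver

One *pass* over a patient's $J$ slices applies, per slice: random walker
→ threshold → keep the connected component containing the foreground
seed (thresholded walker maps can contain detached blobs). The per-slice
masks are accumulated into a cross-slice *ensemble mask* by pixelwise OR
(a majority-vote variant is available via `integrate = "vote"`). After
each pass, new seeds are derived from the ensemble and the pass repeats
— the same seed pair is applied to all slices of a pass — until the Dice
overlap between consecutive ensembles reaches 0.99 or `maxPasses` (5)
have run. A `maxPasses = 2` configuration reproduces the minimal
"segment, re-derive the datapoints, segment once more" reading.

Seed re-derivation (`deriveSeeds()`): the background seed is the pixel
farthest from the ensemble dilated by 5 px, keeping it safely off the
nodule. For the foreground seed the design was genuinely open, and we
chose the mask's **most interior pixel** (the in-mask pixel maximizing
distance to the mask complement, with outside-the-image counting as
complement — an edge-hugging structure must not acquire a spuriously
deep interior) rather than the centroid snapped into the mask. The two rules agree on convex, unattached masks, but when the
ensemble has absorbed an attached structure — typically the pleural wall
— the centroid is dragged toward the attachment and its snapped pixel
can sit at the mask margin. Applied to the outer slices (where the
nodule is smaller), a marginal seed lands in lung parenchyma, and a
foreground seed embedded in the background medium makes the walker claim
roughly the half of the lung nearest it; over passes this runs away to a
degenerate whole-lung attractor. The interior-pixel rule keeps the seed
in the nodule core and is stable on all three nodule classes. All
ties are broken by smallest (row, col), so the derivation is
deterministic.

Degenerate inputs: a slice whose thresholded mask is empty (or whose
foreground-seed pixel is below threshold) contributes nothing to the
ensemble, with a warning; if every slice comes up empty the segmentation
errors rather than returning an empty result, and an empty ensemble at
seed-derivation time raises an "ensemble collapsed" error.

## Radiomic features

Features are computed from the segmented region of each slice, using the
fixed canonical 38-name panel (19 co-occurrence-family, 7
run-length-family, 12 histogram-family; `canonicalFeatureNames()`).

**Quantization.** In-mask intensities are binned to `levels = 64` equal-
width grey levels over the ROI min–max (the conventional range for such
analyses spans 8–256; 64 keeps matrices well populated at nodule sizes
of a few hundred pixels). A constant ROI maps to level 1.

**GLCM.** Pairs at distance 1 along the four offsets 0°, 45°, 90°, 135°,
both pixels in-mask, symmetrized and accumulated into a single matrix,
then normalized. The marginal mean $\mu$ and variance $\sigma^2$ of the
symmetric matrix drive the cluster and correlation features; sum and
difference distributions are indexed $k = 2..2N$ and $k = 0..N-1$.
Entropies use base-2 logarithms with $0\log 0 = 0$. Two feature formulas
are dialect-dependent (see below); correlation and contrast, which have
no published formulas in the source tables, use the standard forms.
Information measures of correlation are implemented as published
(correlation-like, not the classical entropy-based measures); the second
one is read as the covariance sum over $\sigma^2 + 1/\sigma^2$, the
"normalized" variant its description announces. When $\sigma^2 = 0$
(single-level ROI) the correlation-type features are defined as 0, with
a warning.

**Convexity.** A shape feature carried in the co-occurrence family:
per-slice ratio of mask area to the pixelated area of its convex hull
(pixels whose centers lie in or on the hull; collinear masks fall back
to lattice-point counting on the segment), averaged over slices.

**GLRLM.** Maximal runs of constant grey level along each of the four
directions, broken at mask boundaries, accumulated into one
level × run-length matrix. The seven features use the standard forms
(short/long-run emphasis on $p/y^2$ and $p\,y^2$, non-uniformities on
squared marginal run counts over the run total, run percentage
$R_{total}/n_{pixels}$, low/high grey-level emphasis on $p/x^2$ and
$p\,x^2$).

**Dialects.** The published formula set contains several evident
typographic defects (entropies without the minus sign, a sum variance
without its square, a difference variance centred on the wrong
statistic, dissimilarity and homogeneity without absolute values, a
duplicated autocorrelation form, run-length emphases with swapped
weights). The default `corrected` dialect uses the standard forms; the
`printed` dialect evaluates the published formulas verbatim for audit
purposes, except for two run-length formulas (short-run emphasis, run
percentage) whose published forms do not reduce to scalars and which
keep the corrected forms.

**Histogram features.** First-order statistics of the in-mask
intensities pooled over all slices (texture features, by contrast, are
averaged per slice — pooling is the natural reading for first-order
statistics; per-slice averaging of them is one configuration flag away).
Standard deviation and variance use the population ($1/N$)
normalization, kurtosis is non-excess (normal $\approx 3$), entropy uses
a 64-bin equal-width histogram, and skewness/kurtosis of a constant
sample are defined as 0 with a warning.

Features are computed on **raw intensities** by default
(`useRawHu = TRUE`). Interactive contrast adjustment in CT viewers
alters the display, not the voxel data, so extraction on the stored
values is the faithful reading; moreover, computing first-order features
on percentile-clipped values pins the pooled maximum at the clip value
for every patient, which destroys the cohort variance of `hist_max`.
Windowed extraction remains available (`useRawHu = FALSE`).

## Concordance validation

For each canonical feature, the cohort vector extracted from the
segmentation masks is compared with the vector extracted from the
ground-truth masks. Both are ranked with average ranks for ties; without
ties Spearman's coefficient is computed by the classical shortcut
$1 - 6\sum d_i^2 / (n(n^2-1))$, and with ties as the Pearson correlation
of the rank vectors (the two coincide in the tie-free case). A fully
tied vector has no rank variance; its coefficient is undefined and is
reported as flagged `NaN` with strength "none" rather than silently
coerced.

Strength is banded on $|\rho|$ rounded to two decimals — 0 none,
0.01–0.49 weak, 0.50–0.69 moderate, ≥ 0.70 strong — with the direction
reported separately, so a negative coefficient carries the mirrored
strength of its magnitude. A t statistic
$\rho\sqrt{(n-2)/(1-\rho^2)}$ with $n-2$ degrees of freedom accompanies
each coefficient; the p-values are informational and deliberately not
multiplicity-corrected. Per-family selection takes the top 12/6/6
features by $|\rho|$ (ties broken by canonical name order), and the
paired rank vectors are exported per feature for rank–rank scatter
plots.

## The phantom generator

`generatePhantom()` renders a spherical nodule (a pixel is foreground
iff its center lies strictly inside the analytic sphere) of radius $r$
pixels in a uniform lung field, across $J$ slices whose spacing is
chosen so the outermost slices cut the sphere at in-plane radius $r/2$ —
every slice contains nodule, with a comfortable margin. Defaults: a
128 × 128 grid, 5 slices, lung −800 HU, nodule +20 HU, wall +40 HU,
vessel +10 HU, noise sd 20 HU, radius 10 px — CT-like contrast without
any tuning to a particular scanner; the source imaging gives no
intensity statistics for its nodules, so these are engineering choices.
i.i.d. Gaussian noise is added from the case seed and intensities are
rounded to integer HU, as CT scanners store them.

Class geometry:

* **solid** — the sphere alone;
* **juxta_vascular** — a vertical vessel-like cylinder (radius 3 px,
  intensity close to the nodule's), *analytically tangent* to the
  sphere. The cylinder is a finite segment (half-length $3r$): a
  full-height column would cut the lung field in two and strand the
  background seed on the far side, which is a pathology of the phantom,
  not of the method. With center-in-sphere rasterization, tangency
  leaves the structures 8-adjacent but not 4-adjacent on most slices;
  on the middle slice they can touch, which is exactly the hard case
  the class is meant to pose.
* **juxta_pleural** — a bright pleural band (6 px wide) along the right
  image edge, which the sphere overlaps by 2 px. The ground truth is
  the nodule region *excluding* the band.

An optional `lobulation` count adds that many surface bumps of radius
$r/3$ at seeded-random positions on the sphere, giving a lobulated,
non-convex outline. The cohort default uses 3 bumps: a cohort of perfect
spheres has convexity exactly 1 for every patient, leaving the shape
feature without variance (and its rank correlation undefined);
single-phantom defaults keep 0 bumps so the analytic cross-section
areas remain exact.

Initial seeds are analytic: foreground at the truth centroid of the
middle slice, background at the lung-field pixel farthest from the
nodule (restricted to lung so it never lands in wall or vessel).
`generateCohort()` cycles the three classes and draws per-patient nodule
radius from 8–12 px and nodule intensity from 5–35 HU (defaults chosen
as a plausible spread of small solid adenocarcinoma nodules and their
attenuation), with all randomness derived from one master seed.

### What the phantoms do and do not show

The phantoms emulate the *geometry* of the three nodule classes, CT-like
contrast, and additive Gaussian noise. They do not emulate real lung
anatomy (airways, fissures, parenchymal texture), partial-volume
blurring, reconstruction kernels, or inter-scanner variability. Passing
the phantom suite therefore demonstrates that the algorithms are
implemented correctly and behave sensibly on the classes' geometric
hard cases — not that the same Dice or concordance levels would be
attained on clinical data.

## Study conditions and observed behavior

The package's reference experiment (`runAll()` defaults, also what
`scripts/acceptance.R` re-runs) is a 20-patient mixed-class cohort at
noise sd 20 HU. Problem sizes were chosen to keep a full run on a single
CPU within about a minute: 128 × 128 × 5 stacks, ~16k-unknown sparse
solves per slice, 2 passes typical. Under these conditions the noiseless
solid phantom is recovered essentially exactly (per-slice Dice 1.0), and
the pooled per-slice median Dice across the noisy cohort exceeds 0.85.
The per-class picture is uneven in an instructive way: solid and
juxta-vascular cases recover almost perfectly, while juxta-pleural masks
absorb part of the pleural band — wall and nodule differ by only 20 HU,
far below what `beta = 130` can separate after windowing — which is
precisely the juxta-pleural difficulty the nodule taxonomy exists to
name. We report it rather than hide it; a wall-aware prior or multi-seed
background would be the natural extension, and is out of scope.

## Known limitations

* Two-label, slice-wise walker only; no 3-D graph, no multi-label.
* The pleural band adheres to juxta-pleural masks (above).
* DICOM reading supports uncompressed little-endian files of a single
  series and decodes only the tags the pipeline needs; undefined-length
  sequences are rejected.
* TIFF serialization is lossless only for integer-valued intensities
  (which covers CT HU).
* Spearman concordance needs at least 3 patients and is undefined for
  cohort-constant features (reported as flagged NaN, never imputed).
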