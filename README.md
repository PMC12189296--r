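# rwensemble

Random-walker ensemble segmentation of lung nodules in CT, radiomic
feature extraction, and rank-concordance validation against ground
truth — with a deterministic synthetic phantom generator so the whole
pipeline runs and validates without patient data.

## Who this is for

Researchers studying the *reliability* of radiomic biomarkers: the
package measures how well features extracted from an automatic
segmentation agree, across a cohort, with the same features extracted
from reference (ground-truth) masks.

## The methods at its core

**Segmentation.** Each CT slice is a 4-connected lattice graph with
Gaussian intensity weights `w_ij = exp(-beta (g_i - g_j)^2)`. Given a
foreground and a background seed, the random walker assigns every pixel
the probability that a weighted random walk reaches the foreground seed
first — the harmonic solution of the Dirichlet problem on the graph
Laplacian. Per patient, per-slice thresholded walker masks are
accumulated into a cross-slice *ensemble* mask (pixelwise OR), seeds are
re-derived from the ensemble, and the process iterates until consecutive
ensembles agree at Dice ≥ 0.99.

**Features.** 38 canonical features per patient: 19 grey-level
co-occurrence features (including convexity = area / convex-hull area),
7 grey-level run-length features, and 12 first-order histogram features.
Texture features are averaged per slice; histogram features pool in-mask
intensities.

**Validation.** Per feature, Spearman's rank correlation between the
segmentation-derived and truth-derived cohort vectors:
`SCC = 1 - 6 Σ d_i² / (n(n²-1))` (tie-free shortcut; Pearson on average
ranks with ties), banded into none / weak (0.01–0.49) /
moderate (0.50–0.69) / strong (≥ 0.70) with a t test against zero, plus
per-family top-12/6/6 feature selection and rank-pair export for
scatter plots.

## Worked example

```r
library(rwensemble)

# one synthetic juxta-pleural patient with analytic ground truth
case <- generatePhantom(PhantomSpec("P1", "juxta_pleural", noiseSd = 20))
seg  <- segmentPatient(autoWindow(case@stack), case@seeds)
seg
#> EnsembleResult: 2 pass(es), ensemble mask 1060 px; dice trace: 1.0000
mapply(dice, stackSlices(perSliceMasks(seg)), stackSlices(case@truth))
#> [1] 1.0000000 0.3865815 0.4319527 0.3865815 1.0000000

f <- extractPatientFeatures(case@stack, case@truth)
round(f[c("gcm_conv", "gcm_ener", "grlm_rper", "hist_mean", "hist_skew")], 4)
#>  gcm_conv  gcm_ener grlm_rper hist_mean hist_skew
#>    1.0000    0.0020    3.9101   20.6663   -0.0284
```

The per-slice Dice shows the juxta-pleural hard case honestly: outer
slices (nodule clear of the wall) are recovered almost exactly, while
on the middle slices the mask absorbs part of the pleural band, whose
intensity is only 20 HU away from the nodule's. `hist_mean` ≈ 20.7
recovers the phantom's +20 HU nodule; convexity ≈ 1 reflects the
unlobulated sphere.

A full cohort study, end to end:

```r
res <- runAll(outDir = "artifacts")   # 20 mixed-class phantoms, ~1 min
subset(res$concordance, feature %in% c("hist_mean", "gcm_corr", "grlm_lgr"))
#>     feature family    scc direction strength     t       p  n
#>    gcm_corr    gcm 0.7925  positive   strong 5.513 3.1e-05 20
#>    grlm_lgr   grlm 0.8301  positive   strong 6.315 5.9e-06 20
#>   hist_mean   hist 0.7609  positive   strong 4.975 9.8e-05 20
```

`artifacts/` then holds the manifest, both feature tables (CSV), the
concordance table, the selected features, per-feature rank pairs, mask
PNGs and a JSON run report. A command-line front end with subcommands
`phantom`, `segment`, `features`, `concord` and `run-all` is installed
at `exec/rwe`.

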