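---
title: "Linking semantic scores to radiomic features: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking semantic scores to radiomic features: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radsem)
```

## The study design this package implements

Lung tumors on CT can be described two ways: *semantic* features are
qualitative descriptors a radiologist scores by eye — three on a binary
scale (cavitation, air bronchogram, calcification) and six on ordinal
scales (texture, border definition, contour, lobulation, spiculation,
concavity) — while *radiomic* features are quantitative descriptors
computed algorithmically from the segmented tumor volume. The scientific
question is how much the two descriptions overlap: which computed features
track which visual scores, how strongly, and in which direction.

radsem implements that analysis end to end as a four-stage pipeline —
generate (or load) a cohort, extract radiomic features, prune redundant
features, score every (radiomic, semantic) pair — plus a synthetic
CT tumor-phantom generator that serves as a fully controlled cohort, since
no patient imaging ships with the package.

## Radiomic feature extraction

From each volume/mask pair the original image yields 48 features: 13 shape,
12 first-order statistics, 17 gray-level co-occurrence (GLCM), 1 gray-level
size-zone (GLSZM size-zone variability) and 5 run-length (RLGL) features.
Filtered images (by default five Laplacian-of-Gaussian scales at
sigma = 1–5 mm and the 8 sub-bands of a single-level stationary coiflet-1
wavelet transform) each contribute the 12 statistics and 23 texture
features again — geometry is filter-invariant, so shape is computed once.
The default inventory is therefore 48 + 13 × 35 = 503 named features.

Key numerical choices, each fixed and configurable:

* **Discretization.** Texture matrices use fixed 25-HU bins anchored at the
  in-mask minimum (`level = floor((HU - min)/25) + 1`). Anchoring at the
  minimum makes all texture features invariant to global intensity shifts.
  On filtered images the same bin width applies on the filter-response
  scale, and the discretization is recomputed per image.
* **GLCM.** Distance-1 offsets over the 13 unique 3D directions, symmetric
  accumulation, per-direction normalization, features averaged over the
  directions that contain at least one voxel pair. Sum variance is taken
  about the sum average. Correlation on a constant region is undefined and
  reported as `NaN`; downstream statistics exclude `NaN` pairwise.
* **GLSZM.** Zones are 26-connected components of equal gray level;
  size-zone variability is `(1/Nz) * sum_s (sum_g n(g,s))^2`.
* **RLGL.** Maximal same-level runs along each of the 13 directions; five
  features averaged over directions.
* **Surface mesh.** Shape descriptors need a surface area. The mask
  boundary is meshed with a surface-nets construction: one vertex per mixed
  2×2×2 cell at the centroid of its sign-crossing edge midpoints, one quad
  (split as a centroid fan, which preserves grid symmetries) per exposed
  voxel face. The mesh is watertight and consistently oriented, so the
  dimensionless descriptors (sphericity, compactness, spherical
  disproportion) are computed from the mesh's enclosed volume — by the
  isoperimetric inequality sphericity then cannot exceed 1 for any mask.
  The `volume` feature itself and the surface-to-volume ratio use
  voxel-count volume. A digital ball of radius 20 mm at 1 mm spacing scores
  sphericity ≈ 0.974; a naive voxel-face area would be ~50% too large, and
  classic marching cubes on binary data still overshoots by ~8%.
* **Filters.** LoG kernels are exactly sampled continuous Gaussians and
  second derivatives (sigma in mm, converted per axis by the voxel
  spacing), truncated at 6 sigma with the second-derivative taps re-centred
  to zero sum so constants map exactly to zero; responses are scaled by the
  voxel volume. The wavelet transform is undecimated so every sub-band
  stays on the original grid and the tumor mask is reusable unchanged;
  boundaries are mirrored (an optional periodic mode exists, under which
  the orthonormal kernel satisfies Parseval's identity with redundancy 8).
  Sub-band letters follow (x, y, z) axis order.

## Redundancy pruning

All-pairs midrank Spearman correlation, then greedy elimination: while any
retained pair has |rho| ≥ 0.85, take the largest such pair and drop the
member with the larger mean |rho| against the currently retained features.
The iteration order (largest pair first), the mean taken over *currently
retained* features, and lexicographic tie-breaks are deliberate choices to
make the procedure deterministic and order-invariant; correlations
undefined because a feature is constant count as zero, and constant
features are force-dropped with their own reason code. After pruning the
kept set provably contains no pair at or above the threshold (asserted at
run time).

## Association engine

* **Binary scores** (cavitation, air bronchogram, calcification): the raw
  AUC is the midrank Mann–Whitney statistic with the score-1 class as
  "presence". AUC ≥ 0.5 is reported as-is with direction *proportional*;
  AUC < 0.5 is folded to 1 − AUC with direction *inverse*, so the folded
  estimate lives in [0.5, 1]. Significance comes from Noether's asymptotic
  test with the null variance `(n0 + n1 + 1) / (12 n0 n1)` — the classical
  null-hypothesis form; whether to tie-correct the variance is a genuinely
  open choice and the null form is frozen here. Interpretation bins:
  0.5 random, (0.5, 0.7] weak, (0.7, 0.9] moderate, (0.9, 1] excellent.
* **Ordinal scores** (texture, border definition, contour, lobulation,
  spiculation, concavity): midrank Spearman rho for strength and direction,
  tie-corrected Kruskal–Wallis for significance. Bins on |rho|: ≤ 0.5 weak,
  (0.5, 0.7] moderate, (0.7, 0.9] high, > 0.9 excellent.
* **Multiplicity.** Benjamini–Hochberg within each semantic feature's
  family of tests (one semantic column = one family, matching how
  per-figure significance stars are usually assigned); significant means
  q ≤ 0.05. Tests with fewer than 10 usable observations (after pairwise
  `NaN` exclusion) are reported as not evaluated rather than estimated.

## The synthetic phantom cohort

Each subject is a 64³ voxel, 1 mm isotropic CT-like volume: lung
parenchyma at −800 HU, a star-convex tumor of base radius 13 mm whose
radial surface is

r(u) = R · (1 + a_lob · S_low(u) + a_irr · S_mid(u) + a_spic · S_high(u)),

with smooth random angular fields S at low (3–6), intermediate (4–7) and
high (8–14) angular frequency, minus `concavity − 1` spherical bites.
Score-to-knob maps are linear and frozen: lobulation amplitude
0.14·(score−1), spiculation 0.06·(score−1), contour adds anisotropy (axis
ratio up to 1.45) and intermediate-frequency irregularity, bite radius
grows with concavity, border blur sigma is 0.5/1.3/2.1 mm for border
definition 1/2/3, and interiors are −550/−350/+40 HU for
non-solid/part-solid/solid texture. Cavitation carves a −950 HU cavity
(half the base radius) plus eight necrotic pockets at ±150–450 HU around
the interior level — cavitation arises from patchy central necrosis, and
these pockets are what make cavitated tumors measurably more heterogeneous
— and adds a small (+0.08) high-frequency surface-roughness term emulating
the clinical covariance between cavitation and irregular shape (without
it, cavitation would be independent of the mask and no shape association
could exist). Sub-solid interiors keep vessel-like strands and carry extra
voxel-scale speckle (sd 70/40 HU for texture 1/2) because ground-glass
lesions do not obscure the underlying lung architecture; this reproduces
the empirical ordering in which sub-solid lesions are *more* heterogeneous
in size-zone terms than solid ones. Global noise is Gaussian, sd 30 HU.
The returned mask is the rendered tumor support before blurring.

Amplitude constants were calibrated once, on pilot cohorts, so that the
qualitative direction properties hold robustly (sphericity inverse with
cavitation, lobulation, spiculation, concavity; size-zone variability
proportional to cavitation with folded AUC > 0.6; median HU increasing in
texture), and then frozen. Default score marginals are the published
cohort proportions of a 258-patient lung adenocarcinoma study (59%
cavitation, 71% solid texture, 11% calcification, and so on), so sampled
cohorts have realistic class balance.

What the phantoms are *not*: there is no anatomy (ribs, vessels, airway
trees), no scanner physics (reconstruction kernels, beam hardening), and
score-to-morphology coupling is by construction far cleaner than
radiologist scoring of real tumors. Passing direction-recovery tests on
phantoms therefore demonstrates that the pipeline measures what it claims
to measure — not that real cohorts would show effects of the same size.
The air-bronchogram tube (radius 1.2 mm through the tumor) is a free
modelling choice with no quantitative anchor; it is documented, not
fitted.

Reproducibility: every phantom is deterministic given its seed; per-subject
seeds derive from the master seed by `(seed · 1009 + i) mod (2^31 − 1)`.

## Problem sizes used by the shipped checks

The test-suite and the acceptance script exercise: brute-force oracle
comparisons on regions up to 4×4×4 with up to 4 gray levels (exhaustive
pair/zone/run enumeration); a 200-phantom cohort at 64³ for direction
recovery; 100 permutation replicates of 57 independent null features on a
100-subject cohort for the FDR check; and 1000 random feature/label
pairings for the folded-AUC range property. These sizes were chosen so the
full battery runs comfortably on a laptop while keeping the statistical
assertions well-powered (3-standard-error bands).

## Known limitations

* The exact feature identities inside the published 13/12/17/1/5 family
  counts are not printed in the source study's main text; the lists here
  are the standard radiomics definitions, fixed so the counts match and
  every feature named in the study's results (cluster shade/prominence,
  energy, sum entropy, inverse variance, homogeneity, kurtosis, skewness,
  median, minimum, volume, sphericity) is present.
* The published count of filtered features (247) cannot be reconciled with
  any integer combination of the stated family sizes; the filtered
  inventory here is explicit configuration (13 images × 35 features by
  default) rather than a target.
* NRRD support covers the package's own dialect (3D, raw/gzip,
  little-endian); DICOM series and image resampling are out of scope.
* The Noether variance is the null form; with heavy tying and tiny samples
  its p-values are approximate (the q ≤ 0.05 decisions in the shipped
  checks are insensitive to this).
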