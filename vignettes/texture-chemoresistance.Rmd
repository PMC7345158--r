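---
title: "GLCM texture and Taguchi S/N scoring of cell-monolayer images: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GLCM texture and Taguchi S/N scoring of cell-monolayer images: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellglcm)
```

## Scientific model

Chemoresistant (cisplatin-resistant) ovarian carcinoma cells at confluence
pile into rough three-dimensional structures. Optically, the rough surfaces
scatter light, parts of the layer fall out of the focal plane, and cell
margins appear enhanced. A flat wild-type monolayer, by contrast, images as
a smooth, ordered texture. The package's premise is that this morphological
difference is measurable as second-order image statistics, without
segmentation or staining.

The measurement unit is a square patch (default 150 × 150 px) quantized to
`G` gray levels (default 256). For an offset of interpixel distance `d` at
angle `θ`, the gray-level co-occurrence matrix `C(i, j)` estimates the joint
probability of gray levels `i` and `j` at that displacement. Four features
summarize it: contrast `Σ C(i,j)(i−j)²`, energy `Σ C(i,j)²`, homogeneity
`Σ C(i,j)/(1+|i−j|)` and entropy `−Σ C(i,j) log C(i,j)`. Rough, scattering,
margin-enhanced layers raise contrast and entropy and depress energy and
homogeneity; the group comparison therefore tests a signed four-feature
pattern, not a single number.

### Assumptions

* Cells form a near-confluent monolayer, so patches sample cell texture, not
  large empty regions (a foreground filter guards against the latter).
* The two groups are imaged under comparable optics and illumination;
  features are compared in absolute units, with no per-image normalization.
* Cell diameter is roughly 10–20 px at the working resolution, so a single
  offset distance near that scale (default 10 px) captures cell-boundary
  texture.

## Choice of interpixel distance

Texture features vary smoothly with `d` and change regime when `d` crosses
the dominant object size. `sweep_features()` recomputes the features over a
distance grid (default 1–40 px, step 1) and `find_inflection()` locates the
regime change as the first sign change of the discrete second difference of
the 3-point moving-average-smoothed mean curve. Rules fixed here, since any
visual identification of an inflection needs a convention:

* smoothing window: 3 points, endpoints left unsmoothed;
* second differences whose magnitude is below `1e-9` of the curve's maximum
  curvature are treated as zero;
* at a sign change without an exact zero, the grid point with the smaller
  |second difference| is reported; ties go to the smaller distance;
* a curve with no sign change (monotone curvature or a straight line)
  returns the distance of the largest absolute first difference, flagged
  with `inflection_found = FALSE` rather than silently passing.

The acceptance suite checks that on synthetic monolayers with 10–20 px cell
diameters the entropy inflection lands in [8, 25] px, consistent with
setting the working offset near the cell diameter.

## GLCM numerical conventions

* **Angle convention.** 0° points rightward along a row, 90° upward along a
  column; allowed angles are 0/45/90/135.
* **Symmetry.** Each ordered pair is counted in both directions by default
  (`symmetric = TRUE`), the common GLCM practice; asymmetric counting is
  retained for exactness experiments.
* **Normalization.** Counts are divided by the realized pair count, which
  shrinks as `d` grows — never by a fixed constant — so features remain
  comparable across distances. `Σ C(i,j) = 1` is asserted to 1e−12 in tests.
* **Entropy.** `0 · log 0 = 0`; base 2 by default (bits), natural log
  available via `entropy_base = exp(1)`. Published entropy ranges at
  `G = 256` are consistent with either base.
* **Quantization.** `floor(p · G / 2^bit_depth)`, using the fixed bit depth
  rather than per-image min–max, so absolute brightness differences between
  groups survive. An image already expressed on `G` levels passes through
  unchanged, making quantization idempotent.
* **Plug-in estimator bias.** Contrast and homogeneity are linear in
  `C(i,j)` and hence unbiased at any pair count. Energy and entropy are
  nonlinear plug-in estimates with a small pair-count-dependent bias; on
  spatially white noise their distance curves are flat only to ≈ 1% rather
  than to within sampling error. The property tests are written accordingly.

## Composite S/N score

Taguchi signal-to-noise ratios convert "is this group's texture
resistant-like?" into decibels: smaller-is-better
`−10 log₁₀(mean yᵢ²)` for energy and homogeneity, larger-is-better
`−10 log₁₀(mean 1/yᵢ²)` for contrast and entropy.

How four features over `n` patches reduce to one group score is a genuine
design choice; the default (`combiner = "pooled"`) pools the raw values of
the two larger-is-better features into a single larger-is-better evaluation,
the two smaller-is-better features into a single smaller-is-better
evaluation, and averages the two components. This convention, applied to
published group-mean features for the OVCAR-4 wild-type/resistant pair,
reproduces the corresponding published composite scores to within 0.2 dB
(asserted in the acceptance suite via `reference_feature_means()`), which is
why it is the default; exact reproduction is impossible without the original
per-image data, and the other published cell-line pairs deviate by 1–2.5 dB
under any convention tried. A per-feature alternative (mean of the four
per-feature S/N values) is selectable.

Notes on the statistic itself:

* log base 10, the universal Taguchi convention; scores scale by
  ±20 log₁₀ k under multiplication of the inputs by `k`.
* S/N ratios require strictly positive inputs. Zero feature values (e.g.
  contrast and entropy of a perfectly uniform patch) are excluded from their
  pool and reported in `n_excluded`; a group whose pool empties raises an
  error rather than returning a fabricated score.
* Group dispersion is a leave-one-patch-out jackknife standard error of the
  combined score (`group_snr()`), since no standard formula exists for the
  dispersion of a pooled S/N.
* For group *testing*, the score is computed once per image
  (`per_image_snr()`) and the per-image scores are compared by one-way
  ANOVA; images, not patches, are the independent sampling units.

## Group comparison

Classic equal-variance one-way ANOVA (`stats::oneway.test`,
`var.equal = TRUE`); for two groups this is identical to the pooled-variance
t-test (F = t², asserted as a property test). Significance stars use the
0.05 / 0.01 / 0.001 ladder. Raw per-feature p-values are reported with no
multiple-testing correction — the readout is a fixed four-feature signed
pattern plus one composite score, not a feature screen — and this is stated
in the report rather than corrected away.

## The synthetic generator

`render_monolayer()` models only the optical signatures that the analysis
exploits, not cell biology:

| parameter | units | WT preset | CP preset | role |
|---|---|---|---|---|
| `n_cells` | count | 800 | 800 | confluence on a 300 × 300 canvas |
| `radius_range` | px | (5, 10) | (5, 10) | 10–20 px cell diameters |
| `interior_level` | gray | 150 | 150 | cell body brightness |
| `background_level` | gray | 70 | 70 | gap brightness |
| `roughness_amplitude` | gray | 5 | 45 | speckle strength of the rough 3-D interior |
| `speckle_scale` | px | 3 | 3 | speckle correlation length (finer than a cell) |
| `halo_gain` | gray | 8 | 50 | bright 2 px rim emulating scatter/defocus margins |
| `edge_softness` | px | 1.5 | 0.8 | boundary blur (in-focus flat vs sharp margins) |
| `noise_sd` | gray | 3 | 6 | additive sensor noise |

Disks are placed uniformly (overlap allowed), interiors are modulated by a
multiplicative speckle field (low-pass-filtered unit-variance Gaussian noise
via `EBImage::gblur`, rescaled), a 2 px rim annulus is brightened, the scene
is blurred, noise added, and the result clipped to [0, 255] and rounded.
Everything is a deterministic function of the seed; per-image seeds derive
from `(master seed, group index, image index)` through a fixed integer mix,
so each group regenerates independently.

Preset asymmetries (roughness, halo, edge softness, noise) encode the
qualitative morphology contrast between the phenotypes; the presets are
calibrated so the four group-mean features at offset (10, 0°) order as in
real resistant-vs-wild-type data — the package targets that directionality,
never published feature magnitudes, which derive from images that are not
publicly available. Sizes used by the tests and the acceptance script:
300 × 300 px frames, 20 images per group, i.e. 4 patches per frame and 80
patches per group.

Known generator behaviors and limits:

* **Clipping saturation.** Once `interior_level + 3 · roughness_amplitude`
  exceeds 255, speckle clips at the top gray level, probability mass
  concentrates there, and energy stops decreasing with roughness. The
  monotone roughness–response test therefore probes amplitudes 5/15/30,
  inside the dynamic range; the CP preset (45) intentionally sits in the
  clipped, maximally rough regime.
* The generator has no point-spread function, no defocus model beyond the
  rim halo, no illumination gradients, no cell-shape variation beyond disks,
  and no spatial clustering of cells. Passing tests show the pipeline
  recovers a *known* texture contrast with correct directionality and
  calibrated error rates; they do not show that any particular real cell
  line separates, which depends on optics, confluence and phenotype
  strength.

## Patch extraction and image I/O

Frames are tiled into non-overlapping patches on a grid anchored at the
top-left corner (row-major, deterministic), maximizing usable area and
reproducibility. A tile is kept when at least `min_foreground_fraction`
(default 0.2) of its pixels differ from the modal gray level — the
background estimate, appropriate when a blank region is present in the
frame — by more than `threshold` (default 5) levels. Fully confluent
synthetic frames contain no blank region, so the package's own study
pipeline disables the filter (`min_foreground_fraction = 0`). PNG and TIFF,
8- and 16-bit, are read natively; RGB converts by Rec. 601 luminance as a
convenience (monochrome cameras write single-channel files). Float or
palette TIFFs are rejected with an explicit error.

## Reproducibility

All randomness flows from explicit seeds through R's default RNG;
`render_monolayer()` restores the caller's RNG state. The same seed gives
bitwise-identical images, CSVs and reports (asserted by tests). The
acceptance script recomputes the headline group separation — ANOVA on
per-image combined S/N between the two synthetic phenotypes — from scratch
at a caller-supplied seed.
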