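# cellglcm

Texture-based identification of chemoresistant cell phenotypes from plain
bright-field microscopy images.

## The problem

Cisplatin-resistant ovarian carcinoma cells grown at confluence pile into
rough, three-dimensional structures that scatter light and brighten the cell
margins, while their drug-sensitive wild-type parents spread as flat, smooth,
in-focus monolayers. The two phenotypes look almost identical by eye, but
their image *texture* differs systematically. `cellglcm` quantifies that
difference and turns it into a single chemoresistance score, giving a cheap,
fast, label-free readout of resistance risk for cultured cells.

## The method

For a patch quantized to `G` gray levels, the gray-level co-occurrence matrix
(GLCM) `C(i, j)` is the probability that gray levels `i` and `j` co-occur at
a fixed pixel offset `(d, θ)`. Four Haralick-type features summarize it:

    contrast    = Σᵢⱼ C(i,j) (i − j)²
    energy      = Σᵢⱼ C(i,j)²
    homogeneity = Σᵢⱼ C(i,j) / (1 + |i − j|)
    entropy     = −Σᵢⱼ C(i,j) log₂ C(i,j)

Resistant-phenotype images show **higher contrast and entropy** and **lower
energy and homogeneity**. Because texture statistics change characteristically
when `d` approaches the dominant object size, the interpixel distance is set
near the cell diameter (≈ 10–20 px at the working magnification; default
offset `(10, 0°)`), and `sweep_features()` / `find_inflection()` locate that
scale from the data.

The four features are combined into one score with Taguchi signal-to-noise
ratios:

    smaller-is-better:  S/N = −10 log₁₀( mean(yᵢ²) )      (energy, homogeneity)
    larger-is-better:   S/N = −10 log₁₀( mean(1/yᵢ²) )    (contrast, entropy)

The default combiner pools contrast and entropy values into one
larger-is-better evaluation, energy and homogeneity into one
smaller-is-better evaluation, and averages the two components. A higher
combined S/N means "more resistant-like". Groups are compared feature-wise
and score-wise with classic one-way ANOVA and the usual significance stars
(`*` < 0.05, `**` < 0.01, `***` < 0.001).

A seeded synthetic monolayer generator (`render_monolayer()`,
`generate_study()`) emulates the two phenotypes — disks with speckled rough
interiors, scattering rim halos, soft edges and sensor noise — so the whole
pipeline is testable without microscope data.

## Worked example

```r
library(cellglcm)

ds  <- generate_study(20, seed = 1)        # 20 synthetic images per phenotype
tab <- study_feature_table(ds)             # 150x150 patches, offset (10, 0), G = 256
rep <- summarize_groups(tab)
format_report(rep)
```

Output (computed by the code above):

```
group A      group B      quantity       A (mean ± sd)         B (mean ± sd)         p        sig
----------------------------------------------------------------------------------------------------
WT           CP           contrast       1142 ± 146            4730 ± 268            4.51e-148 ***
WT           CP           entropy        11.65 ± 0.182         14.19 ± 0.0536        5.91e-157 ***
WT           CP           energy         0.0006612 ± 0.000101  7.886e-05 ± 1.79e-05  1.28e-99 ***
WT           CP           homogeneity    0.1448 ± 0.00824      0.05431 ± 0.0029      1.32e-139 ***
WT           CP           snr_combined   22.06 ± 0.115         27.18 ± 0.13          3.48e-52 ***

GLCM sampling offset was (10.0); group A is the benchmark.
* p < 0.05, ** p < 0.01, *** p < 0.001.
```

Reading the table: the resistant-like group (CP) has higher contrast and
entropy, lower energy and homogeneity, and a combined S/N about 5 dB above
the wild-type-like group — the sign pattern and significance expected for a
resistant phenotype, each row at `p < 0.001`.

Real images go through the same stages from disk:

```r
cfg <- run_config(distance = 10, gray_levels = 256, patch_side = 150)
cmd_features("my_images/", "features.csv", cfg, labels = "labels.csv")
cmd_compare("features.csv", "comparison.csv", report_file = "report.txt", config = cfg)
```

or from a shell via `inst/scripts/cellglcm-cli.R`
(`simulate` / `features` / `sweep` / `score` / `compare` subcommands).

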