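Package: cellglcm
Title: GLCM Texture Features and Taguchi S/N Scoring for Chemoresistant
    Cell-Monolayer Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the texture of grayscale microscopy images of
    cultured cell monolayers with gray-level co-occurrence matrix (GLCM)
    features (contrast, energy, homogeneity, entropy), sweeps the GLCM
    interpixel distance to locate the characteristic inflection near the
    cell diameter, and combines the four features into a Taguchi
    signal-to-noise (S/N) composite score that separates
    cisplatin-resistant from wild-type ovarian carcinoma phenotypes.
    Includes a seeded synthetic cell-monolayer image generator emulating
    the two phenotypes, one-way ANOVA group comparison with significance
    stars, and a command-line interface wiring the stages into a
    reproducible workflow.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    png,
    tiff,
    EBImage,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
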