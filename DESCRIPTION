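Package: tadfish
Title: Allele-Resolved Analysis of TAD Boundary Proximity and Gene
    Activity from DNA/RNA FISH Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies topologically associating domain (TAD) boundary
    pairing and nascent transcription at the single-allele level from
    high-throughput DNA/RNA FISH imaging. Provides a ground-truthed
    synthetic-data generator, calibrated image stack input/output, nucleus
    segmentation and Laplacian-of-Gaussian spot detection, phase
    cross-correlation channel registration, ploidy-aware quality control,
    closest-neighbor 5'/3' boundary pairing with center-to-center distance
    measurement, nascent-RNA activity classification, interaction-frequency
    scoring, and the nonparametric statistical comparison layer
    (Mann-Whitney, Kolmogorov-Smirnov, Kruskal-Wallis with Dunn-Bonferroni
    post hoc, two-way ANOVA on per-experiment medians, within-nucleus
    allele correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    emmeans,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
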