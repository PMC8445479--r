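Package: adaptscan
Title: Mainland-Island Genome Scans for Local Adaptation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Population-genetic genome scans contrasting two diverged
    populations (e.g. mainland versus island sheep) on SNP-array genotypes:
    PLINK text/binary input and output, sample- and marker-level quality
    control with identity-by-descent pruning, genomic relationship matrix and
    principal components of relatedness, Reynolds genetic distances and a
    neighbor-joining population tree, per-SNP and windowed Weir-Cockerham
    F_ST with empirical-percentile outlier calling, the FLK neutrality test,
    LD scores and nonlinear fitting of the Sved-type LD-decay curve with the
    Hill-Robertson sample-size correction, an EMMAX-style mixed-model
    association scan of binary origin, Moran's I spatial autocorrelation,
    loess-based diagnostic profiles of the selective process around outlier
    loci, and positional candidate-gene lookup. A Balding-Nichols simulator
    with distance-decaying linkage disequilibrium generates synthetic
    two-population datasets with known truth for calibration and power
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    ape,
    phangorn,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
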