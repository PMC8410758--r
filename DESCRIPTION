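Package: orgrowth
Title: Quantitative Analysis of Forebrain-Organoid Overgrowth Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Morphometric quantification of brain organoids from binary image
    masks (projected area, voxel volume, middle-section area) with a linear
    area-to-volume calibration; BrdU/Ki67 labeling-index estimation of
    cell-cycle length and isotropic-fractionation absolute cell counts;
    random-intercept Gaussian mixed models fitted by maximum likelihood with
    likelihood-ratio tests of genotype effects; a permutation-null gene-set
    enrichment framework (annotation-set overlap, rescue direction-reversal
    concordance, principal-component loading enrichment) with a closed-form
    hypergeometric oracle; transcriptome-to-atlas identity mapping by Pearson
    correlation over highly expressed genes; and synthetic-data generators
    that reproduce the statistical structure every stage assumes, so the full
    pipeline is testable without any sequencing or imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr,
    optparse
Config/testthat/edition: 3
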