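Package: ethnocore
Title: Structural-Core Analysis of Medicinal-Plant Free Lists
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for cultural domain analysis of free-list interview data in
    ethnobotany and ethnobiology. Computes Smith's cultural salience index from
    ordered free lists, separates the "structural core" of a domain (items more
    salient than expected by chance) from satellite items via a Monte-Carlo
    null-model salience threshold, and compares core composition between groups
    or time periods with Jaccard dissimilarities, permutational multivariate
    analysis of variance (PERMANOVA), a homogeneity-of-dispersions test and
    principal coordinates analysis. Includes a synthetic free-list generator
    with a planted core for power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils,
    vegan
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
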