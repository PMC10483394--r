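Package: gpmkit
Title: Exhaustive Genotype Pattern Mining for Digenic Trait Detection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Case-control association mining over all pairs of biallelic
    variants and all pairs of genotypes. Implements a likelihood-ratio
    interaction statistic (C = G2_case + G2_ctrl - G2_combined, 4 df) scanned
    over every admissible variant pair, an exhaustive genotype-pair scan with
    support/confidence filtering and exact missing-genotype accounting via
    4x4 cross-tabulations, Haldane-corrected odds ratios, Pearson and Fisher
    exact tests on 2x2 pattern tables, Bonferroni correction with counted
    tests, binned empirical ROC curves for top patterns, a PLINK binary and
    TSV reader, a planted-interaction case-control simulator, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    parallel,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
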