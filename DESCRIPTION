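Package: presnet
Title: Cross-Species Preservation Analysis of Weighted Gene Coexpression Networks
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds weighted gene coexpression networks (biweight
    midcorrelation, soft-threshold adjacency, topological overlap) in a
    reference species, detects modules with a dynamic hybrid tree cut,
    projects the module assignment into a second species, and quantifies
    module preservation by the fraction of genes with sign-consistent
    module membership (kME) together with a label-permutation null and
    composite Z-summary / median-rank statistics. Also provides a
    covariate-adjusted allele-dosage eQTL scan with cis/trans
    classification, conditional analysis and a trans-target enrichment
    test, hypergeometric gene-set over-representation, and a synthetic
    paired-species study generator so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
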