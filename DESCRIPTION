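Package: chickdiv
Title: Genome Diversity and Breeding-Signature Analysis for Resequenced
    Variety Panels
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to study temporal genome-diversity trends in panels of
    re-sequenced crop varieties, modelled on selfing legume panels such as
    chickpea (desi/kabuli market types, release-period cohorts).  Implements
    a depth- and frequency-based variant filtering cascade with genic-context
    and coding-effect annotation (including Nei-Gojobori dN/dS), read-depth
    copy-number segmentation with significance-driven window merging,
    coverage-threshold presence/absence and gene-loss calling, sliding-window
    diversity statistics (pi, Watterson's theta, Tajima's D, Fu and Li's D*),
    Hudson FST / delta-pi differentiation scans and Tajima's-D region scans,
    allele-sharing distances with neighbor-joining trees, Patterson-scaled
    PCA with Tracy-Widom significance, binomial-likelihood admixture EM,
    pairwise LD with decay profiles and Gabriel-style haplotype blocks, and
    a synthetic panel generator with a planted-truth ledger used to validate
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    ape,
    jsonlite,
    yaml,
    Biostrings,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    cluster,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
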