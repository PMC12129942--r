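Package: cotodelim
Title: Integrative Species Delimitation for the Cotoneaster buxifolius Complex
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Re-implements, as a tested pipeline, an integrative
    species-delimitation framework for hybrid-rich plant groups,
    exemplified by the Cotoneaster buxifolius complex: mixed-trait
    (Gower) morphometrics with UPGMA clustering and PCA, post-VCF SNP
    filtering and sliding-window LD pruning, admixture-model ancestry
    estimation by EM with masked cross-validation over K, taxon-level
    gene-pool purity classification, support-thresholded monophyly
    tests on SH-aLRT/UFboot-annotated trees, cytonuclear-discordance
    detection by optimal clade matching, and a hierarchical decision
    cascade labelling taxa as valid species, hybrids, or synonym
    candidates. Includes a Balding-Nichols scenario simulator with
    known truth and an encoder of the study's published per-taxon
    evidence into machine-readable fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    vcfR
Suggests:
    cluster,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
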