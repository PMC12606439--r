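Package: gxemap
Title: Genotype-by-Environment QTL Mapping from Sorted-Pool Bulk Segregant Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for detecting genotype-by-environment
    interactions (GxE) in quantitative cellular traits measured with tandem
    fluorescent timer reporters in a yeast cross. Processes per-cell cytometry
    event tables into gated, drift-corrected activity summaries; tests
    strain-by-environment interactions with mixed models; maps QTLs from
    allele counts of phenotypically extreme sorted pools using a discretized
    hidden-state allele-frequency contrast LOD with 2-LOD support intervals;
    reconciles loci across biological replicates; and classifies locus-level
    GxE into presence/absence and sign-change categories. Includes a synthetic
    yeast-cross generator (Haldane recombination, additive environment-dependent
    QTL effects, truncation selection of phenotypic tails, binomial sequencing
    noise) so the whole chain is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    car
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
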