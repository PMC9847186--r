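Package: triomics
Title: Inheritance-Pattern and Mid-Parent Heterosis Analysis for Parent-Hybrid Trio Omics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for parent-hybrid trio transcriptome and
    metabolome experiments. Provides count normalization (CPM/FPKM) and
    expression filtering, replicate-concordance and PCA diagnostics, a
    negative-binomial Wald test with Benjamini-Hochberg correction, PLS-DA
    VIP scoring for metabolites, mid-parent value construction and
    F1-versus-mid-parent testing, the twelve-type female-hybrid-male
    inheritance classifier with additive / dominance / overdominance
    roll-up, mid-parent heterosis statistics for features and biomass,
    a from-scratch weighted co-expression network stage (soft-threshold
    adjacency, topological overlap, module cutting, eigengenes,
    module-trait correlation), hypergeometric term enrichment, and a
    seeded synthetic trio-omics generator with known inheritance truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    car,
    fgsea,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    DESeq2
Config/testthat/edition: 3
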