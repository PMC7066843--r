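Package: mpscreen
Title: Metaproteomic Drug-Response Screening of Cultured Gut Microbiomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analytical workflow for drug-response profiling of cultured gut
    microbiomes from label-free metaproteomic quantification tables. Peptides
    are assigned to the lowest common ancestor (LCA) of their candidate taxa,
    total and taxon-specific biomass is estimated from summed peptide
    intensity under an equal-volume observation model, and drug effects are
    profiled through absolute/relative abundance contrasts (Wilcoxon rank-sum,
    Benjamini-Hochberg FDR), Bray-Curtis community-shift tests, protein-group
    filtering with log2/quotient normalization and empirical-Bayes batch
    correction, functional aggregation and enrichment (COG/KO/EC,
    hypergeometric), PLS-DA with VIP scores and cross-validated R2/Q2, and
    PerMANOVA. A synthetic metaproteomic data generator with known ground
    truth (biomass scaling, taxon-selective depletion, function-only
    regulation, batch structure, intensity-dependent missingness) supports
    end-to-end validation and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    withr,
    yaml,
    jsonlite,
    sva
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
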