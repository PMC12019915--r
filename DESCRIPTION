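Package: ptmenrich
Title: Posttranslational Modification Enrichment Analysis for Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds a protein-to-PTM-term annotation database from
    Swiss-Prot style flat-file records and the UniProt controlled
    vocabulary of protein modifications, tests protein lists for PTM
    over-representation with the hypergeometric test (singular enrichment
    analysis, SEA), performs GSEA-style protein set enrichment analysis
    (PSEA) on score-ranked protein lists with a permutation null,
    normalized enrichment scores, permutation FDR and leading-edge
    extraction, and exports enriched PTM terms as exact chemical
    modifications suitable for configuring a refined mass-spectrometry
    database search. Includes protein-level scoring from replicate
    intensity tables, modified-peptide occupancy normalization, and a
    synthetic-data generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    fgsea,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
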