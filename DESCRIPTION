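Package: nactmut
Title: Pre- and Post-Neoadjuvant-Chemotherapy Somatic Mutation Comparison
Version: 0.1.0
Authors@R:
    person("Jordan", "Velten", email = "jvelten@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing annotated somatic mutation calls between
    matched tumor samples taken before and after neoadjuvant chemotherapy
    (NACT), motivated by paired-sample studies of high-grade serous ovarian
    carcinoma. Provides per-sample mutation count accounting, pre/post
    shared-mutation fractions by genomic position and by gene, per-case
    stable/emergent/lost gene classification, cross-case recurrence and
    platinum-resistant/sensitive exclusivity sets, multi-site within-case
    comparison, targeted-panel candidate selection with exome-vs-panel
    validation, gene-level copy-number flagging, and a clonal-evolution
    cohort simulator with exact ground truth for oracle testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    VariantAnnotation,
    SummarizedExperiment,
    GenomeInfoDb,
    BiocGenerics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    tools
Config/testthat/edition: 3
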