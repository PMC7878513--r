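Package: beecaste
Title: Comparative Transcriptomics and Gene-Body Methylation of Worker Bee Subcastes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing nurse and forager worker subcastes across
    eusocial bee species. Implements cross-species overlap tests of
    differentially expressed gene sets matched by annotation terms under a
    random-sampling null, rule-based classification of orthogroups into
    taxonomic-conservation categories over a panel of bee datasets,
    context-resolved (CpG versus non-CpG) gene-body DNA methylation
    statistics from per-cytosine bisulfite calls coupled to expression, and
    a minimal Gene Ontology toolkit (ancestor propagation, Fisher
    enrichment against a transcriptome background, level rollups and
    induced subgraphs). A synthetic-data module generates methylomes,
    paired differential-expression tables, orthogroup presence matrices and
    toy ontologies with known ground truth so that every stage of the
    pipeline can be exercised and calibrated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
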