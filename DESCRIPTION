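Package: suppvar
Title: Supplementary-Data Aware Retrieval of Genomic Variant Literature
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how much the supplementary data (SD) attached to
    publications contributes to literature retrieval for genomic variant
    curation. Expands a variant query (e.g. BRAF:V600E) into its equivalent
    descriptions at protein, coding and genomic level plus their syntactic
    surface forms, searches abstract / full-text / supplementary document
    collections through an inverted index, and computes silence-reduction and
    novelty metrics together with clinical-significance contingency analyses.
    Includes a seeded synthetic-corpus generator with known ground truth for
    end-to-end evaluation of the retrieval pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    readxl,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
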