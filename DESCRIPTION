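Package: papt
Title: Pooled Analysis of Protein Truncations in Top-Down Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Meta-analysis of truncated proteoforms reported by top-down
    proteomics studies. Reads proteoform identification lists and canonical
    sequence databases (FASTA, UniProt-style XML), classifies each proteoform
    by truncation state with the start-methionine-excision exception, extracts
    X|X' truncation sites and normalizes their frequencies on the peptide-bond
    background of each dataset, clusters terminus-specific site profiles
    across datasets with Ward's criterion, counts cross-dataset-consistent
    noncanonical termini and matches them to sequence annotation features, and
    runs in-source-fragmentation diagnostics. Includes a seeded generator of
    synthetic proteomes and proteoform lists with known ground truth, plus
    exact analytic oracles for enrichment-recovery checks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    stringi,
    xml2,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
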