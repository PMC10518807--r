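Package: kinicurate
Title: Curation, Aggregation and Analogue-Series Analysis of Kinase Inhibitor Activity Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for curating protein kinase inhibitor (PKI)
    bioactivity records exported from large public databases. Parses two
    tab-separated source dialects, applies record-level qualification filters
    (target category, assay confidence, measurement type, unit normalization,
    comment blacklists, censored-relation handling), standardizes compound
    SMILES (salt stripping, neutralization, stereochemistry removal,
    canonicalization) to a non-stereo canonical merge key, aggregates potency
    per compound-kinase pair in negative decadic logarithmic units with
    consistency filtering, classifies activity at the 10 micromolar threshold,
    extracts analogue series via retrosynthetic fragmentation and
    compound-core relationships, flags covalent warheads by substructure
    search, and writes the four-file deposition schema with summary
    statistics. A seeded synthetic-corpus generator with recorded ground
    truth makes every stage testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
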