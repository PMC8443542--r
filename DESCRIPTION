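Package: barcurate
Title: Assembly, Alignment Trimming and Cleaning of DNA Barcode Datasets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assembles molecular-marker (DNA barcode) reference datasets from
    BOLD- and GenBank-style sources and curates them for downstream use.
    Records from both sources are harmonized into a single total table with
    per-record quality flags, grouped into genus-by-marker FASTA files via a
    marker-synonym parameter table, aligned against a single reference
    sequence with MAFFT and trimmed to the reference extent, and finally
    cleaned by pairwise p-distance outlier detection at the genus and species
    level, stop-codon screening under standard or mitochondrial genetic
    codes, strict AGCT residue filtering, and per-species barcode-gap
    reporting. All network access is behind injectable transports so the
    full pipeline runs offline, and a deterministic synthetic-fixture
    generator with known ground truth supports testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
SystemRequirements: MAFFT (for the alignment stage)
Config/testthat/edition: 3
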