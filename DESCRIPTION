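Package: paleopv
Title: Cross-Species and Ancient-Genome Analysis of DNA Damage Repair Pathogenic Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for asking where the pathogenic variants (PVs) in human DNA
    damage repair (DDR) genes came from. Queries UCSC-style multiple alignments
    at human variant positions and calls per-species allele sharing across
    vertebrate clades; detects catalog PVs in ancient-genome pileups with
    deamination-aware filtering of post-mortem C-to-T / G-to-A damage; compares
    PV content, abundance and carrier timing between modern and ancient cohorts
    (Pearson correlation, Kruskal-Wallis); and classifies per-gene selection by
    pairwise dN/dS (Nei-Gojobori 1986 counting with Jukes-Cantor correction and
    a codon bootstrap). A synthetic-data module generates every input format
    with known ground truth, and summary tables from the published analysis
    ship as plain-text fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    ape,
    phangorn,
    vcfR,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
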