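Package: tripepscan
Title: In Silico Screening of Organellar Proteomes for ACE-Inhibitory Tripeptides
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Mines annotated organellar genomes for angiotensin I converting
    enzyme (ACE) inhibitory tripeptides. Extracts translated protein coding
    genes from GenBank flat files or protein FASTA, classifies them under a
    curated functional-category schema, profiles amino-acid composition,
    scans every protein for tripeptides drawn from an IC50-filtered activity
    database, tabulates matches by C-terminal peptide class and functional
    category with peptide-per-residue densities, annotates matches with
    digestive-protease releasability, and compares two proteomes. Includes a
    seeded synthetic-proteome generator with planted motif occurrences and
    an exact ground-truth ledger for end-to-end validation.
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
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
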