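Package: snopair
Title: Cysteine S-Nitrosylation Site Prediction from Position-Specific
    Dipeptide Propensities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts cysteine S-nitrosylation (SNO) sites in protein
    sequences from 21-residue, cysteine-centered peptide windows. Windows are
    encoded as 39-component pseudo amino acid composition vectors built from
    position-specific dipeptide propensity (PSDP) matrices over nearest and
    next-nearest residue pairs, and classified by a nearest-class-norm rule.
    Includes the full training and evaluation protocol (repeated stratified
    10-fold cross-validation, independent-set testing with leakage checks,
    whole-protein evaluation), Sn/Sp/Acc/MCC metrics in both conventional and
    error-fraction forms, a window redundancy filter, readers and writers for
    peptide tables and FASTA input, a synthetic benchmark generator with
    planted position-specific signal, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
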