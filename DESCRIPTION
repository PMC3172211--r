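Package: mirsvm
Title: Prediction of Mannose-Interacting Residues from Protein Sequence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Residue-level prediction of mannose-binding sites in proteins.
    Chains are annotated from protein-mannose complexes (any heavy atom within
    a distance cutoff of a mannose heavy atom), turned into overlapping
    fixed-length residue windows, encoded as binary one-hot, normalized PSSM,
    or amino-acid composition profiles, and classified with a radial-basis
    support-vector machine carrying an asymmetric class cost. Includes
    stratified five-fold cross-validation with threshold-swept sensitivity,
    specificity, accuracy and Matthews correlation, ROC/AUC, compositional
    enrichment analyses, a synthetic-chain generator for offline testing, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
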