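Package: ggapfs
Title: g-Gap Dipeptide Composition, F-Score Feature Selection and SVM
    Classification for Protein Sequences
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Two-class protein sequence classification from primary sequence
    alone. Computes g-gap dipeptide composition features (the 400 ordered
    residue pairs separated by g intervening residues), ranks features by a
    two-group ANOVA F-score with a signed min-max normalization, selects an
    optimal feature subset by incremental feature selection driven by
    cross-validated overall accuracy of an RBF-kernel support vector machine,
    and reports sensitivity, specificity and overall accuracy under
    stratified k-fold and jackknife cross-validation. Includes residue
    preference matrices for enrichment analysis and a seeded synthetic-data
    generator that plants g-gap dipeptide signal at controlled effect sizes
    so the whole pipeline can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    e1071,
    graphics,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
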