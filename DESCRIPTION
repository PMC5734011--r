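Package: cassex
Title: Sequence-Feature Classification of Cassette and Constitutive Exons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for distinguishing cassette (skipped) exons from
    constitutive exons in genomic sequence. Provides strand-aware
    extraction of exon bodies and intronic flanks from FASTA, a
    maximum-entropy splice-site strength model with paired signal and
    decoy distributions scored by log-odds, a 91-feature extractor
    (length, mono/di/trinucleotide composition, GC content,
    termination-codon frequencies, donor and acceptor splice-site
    strengths), a conditional-inference forest classifier with
    out-of-bag permutation variable importance (conditional and
    unconditional), k-nearest-neighbour and Gini random-forest
    baselines, stratified cross-validation with ROC/AUC and
    sensitivity/specificity/total-accuracy metrics, group-wise feature
    comparison tests, and a synthetic genome generator with planted
    class differences for fully offline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    randomForest,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
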