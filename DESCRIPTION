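Package: syncodon
Title: Context-Dependent Synonymous Codon Prediction and Gene Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns context-dependent synonymous codon usage from a corpus of
    coding sequences and uses it to back-translate proteins into host-tuned
    genes. Genes are decomposed into sliding peptide windows of five or seven
    residues; a codon selection index records, for every observed fragment,
    the codon distribution of its middle residue and the mean codon usage at
    each fragment position. Query fragments are scored against the index with
    a substitution matrix (matched percent p = s/m), and per-amino-acid
    random-forest classifiers trained over a grid of match cut-offs and
    window sizes predict the codon at each position, including conserved
    rare codons that frequency-only optimizers miss. Includes corpus
    filtering with identity-based redundancy removal, ten-fold
    cross-validation of the classifier grid, a synthetic corpus generator
    with planted context rules for end-to-end validation, and a gene-design
    pipeline with positional tables for gene termini.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    randomForest,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
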