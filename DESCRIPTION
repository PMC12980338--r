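Package: promtok
Title: Tokenization, Negative-Set Design and Evaluation for Promoter
    Sequence Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale framework for building and evaluating
    transformer-based promoter classifiers on TSS-centered DNA windows.
    Provides a multi-organism synthetic promoter corpus generator with
    planted core-promoter motifs and phylogeny-correlated background
    composition; two auditable negative-set strategies (segment-shuffled
    promoters and distance-constrained genomic fragments); identity
    clustering with a leakage-free size-ascending train/validation/test
    split; four DNA tokenization schemes (overlapping and non-overlapping
    k-mer, byte-pair encoding, WordPiece) plus a character baseline, all
    with nucleotide-span tracking; a small bidirectional self-attention
    encoder with masked-language-model pretraining under flat or
    evolutionary-informed curricula and binary fine-tuning; positional
    attribution profiles over TSS-relative coordinates; and an evaluation
    layer with AUC, the DeLong test for correlated ROC curves,
    Benjamini-Hochberg FDR control and Pearson correlation tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
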