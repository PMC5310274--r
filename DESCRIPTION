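Package: rnnbias
Title: Sequence-Specific Bias Correction for RNA-Seq Using Recurrent
    Neural Network Language Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Corrects sequence-specific bias in RNA-seq read counts by
    modelling the nucleotide context around read 5'-end positions with
    character-level recurrent neural network language models (vanilla RNN,
    GRU, LSTM) trained by backpropagation through time. Foreground models
    are fit on context windows centred on observed read starts and
    background models on randomly offset windows; the per-site bias weight
    is the ratio of foreground to background sequence probability, and
    gene-level FPKM values are computed from bias-reweighted counts.
    Includes readers for FASTA, BED12, SAM and a read-start TSV dialect, a
    synthetic-data simulator with a known injected positional-weight-matrix
    bias, evaluation metrics, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
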