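Package: strandscan
Title: Strand-Symmetric Convolutional Networks for Regulatory Region
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts gene regulatory regions (open chromatin,
    transcription-factor binding) from double-strand genome sequence with
    forward- and reverse-sequence scan (FRSS) convolution layers, in which
    the reverse-strand stream reuses 180-degree-rotated copies of the
    forward kernels so both DNA strands share one set of weights. Includes
    the full data-structuring pipeline (genome windowing, peak-summit
    labelling, negative downsampling), a from-scratch trainable network
    with the alternating sub-mini-batch schedule and F1-triggered
    checkpointing, chromosome-holdout evaluation (AUROC/AUPRC),
    interpretability tools (class saliency, in silico mutagenesis,
    activation maximization, kernel-to-motif export in MEME format), the
    coverage-corrected fraction-of-reads-in-peaks (cFRiP) quality metric,
    and a synthetic-genome generator with planted motifs for ground-truthed
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo: Rcpp
RoxygenNote: 7.3.3
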