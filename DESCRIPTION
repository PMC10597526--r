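Package: lfnetr
Title: Coding-Potential Prediction with Local Filter Networks and
    Translation-Task Sequence Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for predicting the protein-coding potential of RNA
    transcripts with sequence-to-sequence neural models.  Implements the
    Local Filter Network (LFNet) encoder layer, a short-time-Fourier
    token mixer with learned complex frequency-domain filters; an
    encoder-decoder architecture with classification, translation,
    position-weighted translation and start-pointer training objectives;
    beam-search decoding with CDS detection by global alignment;
    mutation-effect prediction by saturated in silico mutagenesis and its
    gradient-based approximations (first-order Taylor, Integrated
    Gradients, Mutation-Directed Integrated Gradients); and an
    importance-driven interpretation pipeline (metagenes, motif-window
    extraction for MEME-suite tools, region-shuffle and knockout
    perturbation scans).  A synthetic transcriptome generator provides
    desk-scale corpora with the statistical structure the models must
    detect.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
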