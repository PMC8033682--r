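Package: domainCNN
Title: Protein Domain Classification in Error-Prone Long Reads with
    Convolutional Neural Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Alignment-free classification of protein domains directly from
    error-containing long sequencing reads (PacBio/Nanopore style). Each DNA
    read is translated in its three forward reading frames, one-hot encoded
    into a 3-channel tensor, and classified by a multi-filter-size
    convolutional neural network with max-over-time pooling; the reverse
    complement supplies the remaining three frames. Reads that carry none of
    the trained domain families are rejected open-set style via a calibrated
    threshold on the maximum softmax probability, optionally sharpened during
    training by an Outlier Exposure penalty that pushes out-of-distribution
    reads toward a uniform softmax. Includes a synthetic family/read simulator
    (planted conserved motifs, reverse translation, per-base
    substitution/insertion/deletion errors) so the full pipeline is trainable
    and testable at desk scale, plus evaluation utilities: detection
    recall/precision/micro-F1, frame-order permutation experiments, and
    extraction of the peptide fragments that activate convolutional filters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    jsonlite,
    yaml,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
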