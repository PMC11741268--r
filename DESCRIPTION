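Package: rampvar
Title: Variant Effects on 5' Ramp Sequences Under Tissue-Specific Codon Adaptiveness
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects 5' ramps of slowly translated codons in coding sequences
    from sliding-window harmonic means of tissue- or cell-type-specific codon
    translational efficiencies, classifies how single-nucleotide variants alter
    those ramps across many tRNA contexts (loss, gain, size change), computes
    accompanying codon-usage-bias metrics (GC content, identical codon pairing,
    codon aversion, within-family codon rank), and implements a delta-delta-Ct
    qPCR and ELISA expression-statistics workflow.  A synthetic-data generator
    with controllable ground truth (planted ramps, ramp-destroying synonymous
    variants, replicate-structured Ct data) makes every stage testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
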