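Package: biomemory
Title: In Silico DNA Memory: Genomic Pattern Learning and Associative Recall
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates a DNA-computing "biological memory" pattern classifier.
    A library of 40-nt memory tags (a fixed 20-base non-crosshybridizing tag
    plus a 20-base random probe) learns the content of genomic DNA in vitro by
    random-probe primed extension: probe-template annealing, Klenow 3'-trim
    plus 5'->3' extension, exonuclease digestion of unbound strands, and
    affinity bead separation. Learned pools are recalled associatively by
    simulated microarray hybridization with background-subtracted intensity
    and signal-to-noise readout. Includes nearest-neighbor duplex melting
    temperature calculations with monovalent and magnesium salt corrections,
    a synthetic genome and DNase I fragmentation simulator, k-mer commonality
    analytics between genomes, and end-to-end experiment drivers for protocol
    ordering, annealing-temperature sweeps, two-strain discrimination, and
    mixture titration sensitivity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    ggplot2,
    generics,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
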