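Package: dominoArray
Title: Single-Molecule Analysis of Allosteric Transformation Cascades in
    Reconfigurable DNA Origami Arrays
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the stepwise, allosteric transformation
    reaction of reconfigurable DNA origami domino arrays at the
    single-molecule level. Provides a lattice kinetic Monte Carlo
    simulator of the anti-junction cascade driven by an energy landscape
    over open anti-junction intermediates, a renderer that turns
    simulated cascades into realistic dual-color turn-on FRET time-lapse
    movies, an image-analysis chain (fiducial-based drift correction,
    channel registration, appearing-spot detection, transient
    extraction, colocalization), a two-state Gaussian hidden Markov
    model for transformation-time extraction with a minimum-dwell rule,
    and statistics for mechanochemical coupling (the coupling parameter
    C, transformation time differences, fluctuation fractions,
    transformation yield, nearest-neighbor duplex energetics and
    transport-efficiency titrations).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    tiff,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
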