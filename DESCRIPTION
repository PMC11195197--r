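Package: fbepair
Title: Adjacent FBF-Binding-Element Discovery and Quantitative Binding Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to discover pairs of adjacent FBF binding elements (FBEs)
    in CLIP peak sequences from C. elegans germline PUF-protein targets, and to
    quantify the protein interactions that act through them. Implements exact
    degenerate-consensus scanning for four FBE classes (canonical FBE, compact
    FBE, and two FBEa*-like variants), pairing of elements under a spacing
    constraint, peak-height statistics, a one-set-of-sites isothermal titration
    calorimetry model (simulation and fitting), EMSA fraction-bound curve
    fitting, FRET efficiency, thermodynamic conversions, and quantitation of
    germline protein-intensity profiles along the distal-proximal axis. A
    synthetic-data generator with known ground truth drives every stage at
    desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
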