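Package: rhythmnet
Title: Functional Connectivity Analysis of Rhythmic Spiking Networks on
    Multi-Electrode Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for reconstructing functional connectivity in rhythmic
    (central-pattern-generator style) spiking networks recorded on
    multi-electrode arrays, with the pre-Botzinger inspiratory network as
    the motivating system.  Provides a ground-truthed synthetic recording
    generator (population bursts, unit and multi-unit elements, planted
    pairwise couplings, condition effects such as hypoxia or isocitrate),
    band-pass filtering and threshold spike detection, PCA plus
    Gaussian-mixture spike sorting with refractory-period quality control,
    rate-normalized cross-correlograms with a flank-noise significance
    rule, per-condition linkage matrices and their differences
    (delta-correlation), and network-level summaries, statistics and
    graph export.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    mclust,
    igraph,
    jsonlite,
    multcomp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
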