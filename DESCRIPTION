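Package: chromsm
Title: Markov State Models of Chromatin Organization from Hi-C Contact Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds Boltzmann-flux Markov state models from binned Hi-C
    contact maps and analyses their metastability to partition chromosomes
    hierarchically. Contact counts are read as sparse triplet text, smoothed
    with a truncated Gaussian kernel, and converted to a contact-energy
    landscape whose annealed random walk exposes separated kinetic time
    scales. Mean first-passage times, recurrence times and pairwise
    committors drive a Monte-Carlo optimization of a metastability index
    over hub sets; committor probabilities turn optimal hub sets into soft
    and hard partitions at each level of hierarchy. Effective interactions,
    observed-over-expected affinities, partition-scheme mutual information,
    and epigenomic overlays (signal-track z-scores, Giemsa-band chromatin
    classes, enrichment regressions) complete the coarse-grained description
    of chromosome and genome architecture. A deterministic hierarchical toy
    chromosome generator with known nested basins is included for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
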