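Package: octodart
Title: Dominant-Marker Genotyping Analysis for Octoploid Strawberry DArT/DArTseq Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for presence/absence (dominant) DArT and DArTseq
    markers in polyploid crops, centred on octoploid strawberry. Implements the
    single-dose (simplex) marker classification and filtering cascade used to
    assemble pseudo-testcross F1 linkage maps (chi-square segregation tests,
    missing-data and read-depth filters, redundancy collapse), dominant-marker
    diversity statistics (polymorphism information content, call rate and
    reproducibility, Nei-Li restriction-fragment distances, neighbour-joining
    phylograms with bootstrap support, principal coordinates analysis, and the
    Evanno delta-K model-selection statistic), two-point linkage and LOD
    grouping, genetic-map summaries, and genetic-versus-physical synteny
    comparison (chromosome concordance and inversion detection by longest
    monotone subsequences). Includes seeded simulators for octoploid F1 crosses
    under disomic inheritance and for structured diversity panels, so that
    every stage is testable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    jsonlite
Config/testthat/edition: 3
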