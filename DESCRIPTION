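Package: rushscreen
Title: Simulation and Analysis of Nuclear-Retention Biosensor Translocation Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end toolkit for high-content screens that read out
    nucleo-cytoplasmic translocation of a hook-retained fluorescent reporter
    in 384-well plates. Generates seeded, ground-truthed synthetic plates
    (punctate-retained, diffuse-nuclear, translocated and pyknotic cell
    phenotypes rendered into multichannel fields), segments nuclei and
    cytoplasmic regions, measures per-cell reporter intensity, granularity
    and nuclear pyknosis, summarizes wells, performs intra-plate ratio
    normalization and inter-plate Z-scoring, classifies compounds by the
    two-condition (release-cue) differential logic, ranks hits, and clusters
    response profiles with average linkage on Pearson distance.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    Rcpp,
    ape,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    withr,
    yaml,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
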