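Package: spiralml
Title: Tremor Severity Analysis of Digitized Archimedes Spiral Drawings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for essential-tremor severity assessment from
    digitizer spiral-drawing trajectories. Reads and writes plain-text tablet
    trajectory files, simulates tremor-graded Archimedean spiral cohorts,
    transforms drawings into radius and discrete-cosine-transform residue
    series, quantifies group consistency through correlation matrices and
    Mann-Whitney U tests, and classifies severity levels with a
    PCA-LDA-classifier stack evaluated under leave-one-out, k-fold,
    stratified, hold-out and Gaussian-noise validation schemes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    MASS,
    e1071,
    class,
    randomForest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
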