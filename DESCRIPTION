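Package: koalawalk
Title: Behaviour Classification and Ground-Visit Analysis for Arboreal Mammal Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for tri-axial collar accelerometry of
    arboreal mammals, developed around koala (Phascolarctos cinereus)
    biologging. Generates behaviour-annotated synthetic 50 Hz collar streams
    with semi-Markov bout structure and a diel ground-visit process; reads,
    validates and down-samples raw streams; extracts windowed statistical
    features and Vectorial Dynamic Body Acceleration (VeDBA); trains and
    evaluates a chronologically stratified Random-Forest behaviour classifier;
    smooths per-second labels with a modal filter and blip collapse into 20 s
    behaviour bins; clusters Walking bins into Ground Visits and computes
    rescaled daily behavioural budgets; and models diel activity with cyclic
    smooths and mixed models.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lmerTest,
    mgcv,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    zoo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
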