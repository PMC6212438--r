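Package: odorpanel
Title: Odorant-Receptor Panel Vapor Detection and Discrimination Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of real-time cAMP reporter (GloSensor-style)
    plate assays for panels of odorant receptors (ORs). Generates synthetic
    96-well kinetic luminescence runs for a 31-OR + vector-control panel under
    liquid or vapor-phase odorant stimulation, including Hill-type dose
    response, esterase (Ces1d-style) substrate conversion and high-dose
    toxicity attenuation. Implements vector-control trace normalization,
    AUC/peak response quantification, a dual-luciferase screening cascade
    (fold-change ranking plus triplicate t-test confirmation), the inferential
    toolbox used for such panels (one-way ANOVA, Tukey HSD differential
    activation counts, Dunnett onset analysis, Benjamini-Hochberg FDR,
    regression R-squared), and odor discrimination by cross-day random-forest
    and LDA classification with t-SNE visualization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    MASS,
    multcomp,
    randomForest,
    Rtsne,
    minpack.lm,
    pheatmap,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
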