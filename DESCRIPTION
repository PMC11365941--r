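Package: SpineCompete
Title: Resource-Competition Modelling of Multi-Spine Structural Plasticity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling competitive structural plasticity across
    dendritic spines stimulated along a shared dendrite. Implements a 1-D
    reaction-diffusion model of a fast potentiating resource and a slow
    dual-role resource with spatial competition among stimulation sites,
    gradient-based (discrete adjoint) multi-start least-squares fitting of
    the model to normalised spine-volume time courses, goodness-of-fit
    metrics (snapshot-averaged NMSE and variance-weighted R squared),
    bootstrap exponential-decay analysis with Kruskal-Wallis/Dunn/FDR
    comparisons, and a synthetic cohort generator for parameter-recovery
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
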