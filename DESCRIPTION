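Package: wiseplan
Title: Preprocedural Planning for Leadless Left Ventricular Endocardial Pacing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale planning pipeline for leadless left-ventricular (LV)
    endocardial pacing with an ultrasound transmitter (WiSE-CRT). From a
    CT-derived LV anatomy the package measures wall thickness with thin
    (<5 mm) labelling, quantifies dynamic-perfusion myocardial blood flow and
    perfused capillary blood volume by compartment-model deconvolution of
    time-attenuation curves, extracts per-segment time-to-peak contraction
    from endocardial motion, simulates electrical activation from the right
    ventricular pacing site with a surface first-arrival (eikonal) model,
    fuses these into the rule-based selection of two adjacent target segments
    for electrode implantation, ranks intercostal transmitter sites by a
    depth/angle acoustic-intensity model, and evaluates acute hemodynamic
    response (percent change in dP/dt max) with group comparisons. A seeded
    synthetic-patient generator reproduces the statistical structure of the
    study cohort so the whole pipeline is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    patchwork,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
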