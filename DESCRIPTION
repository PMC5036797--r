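Package: copdnet
Title: Immune-Network ODE Model of Cigarette-Smoke-Induced COPD Progression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multiscale ordinary-differential-equation model of the
    cigarette-smoke (CS) induced immune response in the progression of
    chronic obstructive pulmonary disease (COPD). The model couples eight
    immune-cell populations (M1/M2 macrophages, dendritic cells, Th1, Th2,
    CD8+ T, Th17 and regulatory T cells), nine cytokines (IL-4, IL-6,
    IL-10, IL-12, IL-17, IL-21, TNF-alpha, IFN-gamma, TGF-beta) and a
    lung tissue-damage fraction through Hill-function regulation. The
    package provides a stiff-capable simulation engine with
    piecewise-constant smoking protocols, an in-silico experiment battery
    (dose-response, smoking cessation, susceptibility sweeps, element
    knockouts, feedback-loop breaking and activation), Latin hypercube
    sampling with partial-rank-correlation (PRCC) global sensitivity
    analysis, and a synthetic virtual-smoker cohort generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    lhs,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
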