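Package: coilflow
Title: Porous-Media Hemodynamics and Recurrence Prediction for Coiled
    Cerebral Aneurysms
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Desk-scale computational hemodynamics of coil-embolized
    cerebral aneurysms. Generates idealized sidewall and terminal aneurysm
    geometries, solves steady and pulsatile incompressible laminar blood
    flow on a staggered grid with a Darcy-Ergun porous momentum sink
    standing in for the coil mass, and post-processes wall shear stress,
    neck-plane inflow/outflow zones and the residual flow volume (RFV)
    statistic. Includes a synthetic cohort generator with the group
    structure of published coiling series and the complete recurrence
    prediction workflow (Mann-Whitney screening, Spearman collinearity
    pruning, stepwise backward logistic regression, ROC analysis).
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    pROC,
    stats,
    tools,
    utils
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
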