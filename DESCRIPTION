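Package: psadapt
Title: Clonal Evolution and Resistance-Informed Therapy Scheduling for
    Bone-Metastatic Prostate Cancer
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Discrete-time simulator of bone-metastatic prostate cancer as
    six competing phenotypes (treatment-naive and five resistant clones)
    sharing one logistic carrying capacity, with serum PSA as a linear
    proxy for total tumor burden. Daily updates apply clone-specific
    logistic growth, treatment kill fractions, and mutation-driven
    emergence of resistance under first- and second-generation androgen
    deprivation therapy, chemotherapy, bisphosphonate palliation, and
    one-time debulking (surgery/radiotherapy). Includes grid-search
    calibration of a patient's initial naive:resistant heterogeneity from
    sparse PSA histories, a cyclic resistance-informed treatment scheduling
    algorithm that targets the largest susceptible subpopulation, a
    virtual-patient generator for in silico evaluation, and a command-line
    interface over CSV/JSON patient records and YAML/JSON configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
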