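Package: crcscreen
Title: Markov Cohort Cost-Effectiveness Modelling of Colorectal Cancer Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic annual-cycle Markov cohort model for comparing
    population colorectal cancer screening strategies: annual faecal
    immunochemical testing (FIT) followed by conventional or AI-assisted
    colonoscopy, and direct conventional or AI-assisted colonoscopy, against
    no screening.  Implements the screening pathway state machine (annual FIT
    re-offer, ten-year post-normal hiatus, three-year adenoma surveillance),
    life-table based accounting of cancer-related life years lost, discounted
    cost breakdowns by category, incremental cost-effectiveness ratios with
    dominance analysis, and deterministic one-way/two-way sensitivity
    analyses with threshold detection.  A seeded per-individual
    microsimulation is included as an independent cross-check of the cohort
    recursion, and a Gompertz-Makeham generator provides a synthetic
    high-longevity standard life table.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
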