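Package: crcscreen
Title: Cost-Effectiveness Modelling of Population-Based Colorectal Cancer Screening
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A Markov cohort state-transition model of the colorectal
    adenoma-carcinoma sequence with a screening and surveillance overlay for
    guaiac faecal occult blood testing (with reflex faecal immunochemical
    testing), primary faecal immunochemical testing, and once-only flexible
    sigmoidoscopy. Natural-history transition probabilities are calibrated to
    incidence, mortality and prevalence targets by Metropolis-Hastings MCMC.
    An economics layer converts state occupancy and event tallies into
    discounted costs and quality-adjusted life-years, incremental
    cost-effectiveness ratios and efficiency frontiers with strict and
    extended dominance; an uncertainty layer provides one-way sensitivity
    analyses, probabilistic sensitivity analysis, tornado tables and
    cost-effectiveness acceptability curves. Synthetic life tables and
    calibration targets with known truth support end-to-end testing without
    external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
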