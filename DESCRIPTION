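Package: tricotkit
Title: Design, Analysis and Reporting for Triadic On-Farm Trials (tricot)
Version: 0.1.0
Authors@R: person("Tricotkit", "Developers", role = c("aut", "cre"),
    email = "maintainers@tricotkit.org")
Description: Tools for decentralized on-farm trials based on triadic
    comparisons of technology options (tricot). Generates approximately
    A-optimal, sequentially and position-balanced incomplete block designs
    with blocks of three, converts best/worst responses into (partial)
    rankings, fits Plackett-Luce worth models with optional
    pseudo-comparison regularization, detects covariate-driven preference
    heterogeneity with likelihood-ratio Plackett-Luce trees and
    cross-validated forward selection, computes agro-climatic covariates
    from daily weather, and renders overview reports plus personalized
    participant result sheets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
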