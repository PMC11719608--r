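Package: chocrisk
Title: Dietary Cadmium Exposure and Health Risk Assessment for Chocolate Products
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Deterministic and probabilistic assessment of dietary cadmium
    exposure from milk and dark chocolate consumption. Computes estimated
    weekly intake (EWI), percentage of the provisional tolerable weekly
    intake (%PTWI), the non-carcinogenic hazard quotient (HQ) and the
    incremental lifetime cancer risk (CR) for seven consumer groups;
    checks concentrations against EU maximum residue levels; propagates
    parameter uncertainty through the HQ and CR models with a seeded
    Monte Carlo engine (point, triangular and lognormal inputs); ranks
    input factors by contribution to output variance via normalized
    squared Spearman rank correlations; and generates synthetic
    per-sample concentration datasets from published group summary
    statistics via truncated lognormal fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
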