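Package: nitromit
Title: Meta-Analysis and Cost-Benefit Assessment of Cropland Nitrogen
    Mitigation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A pipeline for assessing measures that reduce nitrogen
    pollution from croplands. Estimates treatment effects of field
    management measures on nitrogen losses, yield and nitrogen use
    efficiency via unweighted log response-ratio meta-analysis with
    bootstrap confidence intervals; computes regional cropland nitrogen
    mass balances and nitrogen use efficiency; translates measure
    efficacies and adoption rates into emission-factor based abatement
    potentials; monetizes implementation costs and ecosystem, health,
    yield and climate benefits with Monte-Carlo uncertainty propagation;
    and projects cropland nitrogen budgets to mid-century under tiered
    adoption scenarios. Includes a synthetic-data generator with known
    ground truth so the full chain can be exercised and validated without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
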