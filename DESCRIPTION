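Package: paircoord
Title: Biparental Foraging Coordination from Saltwater Immersion Loggers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying coordination of biparental care in central-place
    foraging seabirds from leg-mounted saltwater immersion loggers. Parses both
    common logger dialects (10-minute binned wet seconds and wet/dry state
    changes) into wet/dry bout sequences, extracts foraging trips and nest
    attendance shifts, infers the untagged partner's trips from the tagged
    bird's attendance, detects hatch dates from the drop in trip duration,
    builds a partner previous-trip deviation covariate measuring within-pair
    coordination, and fits stage-specific linear mixed models with AICc-based
    multimodel selection, nested-model exclusion and conditional model
    averaging. Includes a paired-schedule simulator with known trait effects
    and coordination slopes so every stage of the pipeline can be validated
    against ground truth.
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
    jsonlite,
    lme4,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
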