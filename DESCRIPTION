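Package: umicollide
Title: Duplex Consensus Calling with UMI and Mapping-Position Read Grouping
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulation and analysis toolkit for comparing mapping-position-based
    and unique-molecular-identifier (UMI) based read grouping in duplex consensus
    variant calling. Includes a synthetic paired-end read generator emulating
    fresh-frozen, FFPE and cell-free DNA fragmentation with strand-tracked PCR
    duplicates and double-stranded UMIs; position and position-plus-UMI read
    grouping with single-mismatch UMI clustering; duplex consensus collapsing;
    threshold-based variant calling with sensitivity, false positives per
    kilobase, ROC and AUC metrics; closed-form binomial detection and molecular
    count models; and collision-rate, in-silico dilution and variant signal-loss
    analytics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
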