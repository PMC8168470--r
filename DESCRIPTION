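Package: tregmine
Title: Cross-Dataset Mining of Regulatory T Cell Transcriptomes and Secretomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for threshold-based differential expression calling with
    housekeeping-gene quality control, decomposition of differentially
    expressed genes against secretome catalogs and curated gene panels,
    direction-aware pathway activation calls with shared/specific/dual
    accounting across dataset groups, regulator collaboration-quadrant
    classification against knockout or antibody-blockade contrasts, dual
    knockout ROS regulatome construction, and group-level statistics. Includes
    a deterministic synthetic-data generator with planted ground truth so the
    whole pipeline is testable without external downloads.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
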