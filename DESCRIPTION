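Package: gagomics
Title: Region-Level Glycosaminoglycan Disaccharide Profiling and
    Differential Omics Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tidy tools for intra- and intertumoral region comparison of
    glycosaminoglycan (GAG) disaccharide profiles and label-free protein
    quantification matrices. Parses Lawrence-code chondroitin sulfate (CS)
    and heparan sulfate (HS) disaccharides including co-eluting composite
    peaks, derives sulfation statistics (relative composition, total
    amount, average rate of sulfation, 6S/4S ratio, N/O sulfation ratios),
    performs exact rank-sum differential abundance testing suited to very
    small groups with quantification filters and fold changes, and runs
    Ward.D2 hierarchical clustering and scaled principal component
    analysis of the resulting feature matrices. Ships a seeded synthetic
    cohort generator with planted ground truth for end-to-end validation.
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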