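Package: refstab
Title: Reference Gene Screening and RT-qPCR Stability Ranking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies candidate reference (housekeeping) genes from
    transcriptome TPM matrices by coefficient-of-variation screening on the
    log2 scale, validates panels of candidates with the four standard
    RT-qPCR stability statistics (geNorm M value and pairwise variation,
    NormFinder model-based stability, BestKeeper descriptive statistics and
    index correlation, and the comparative delta-Ct method), combines the
    four rankings by their geometric mean into a comprehensive stability
    order, and fits the linear calibration between log2(TPM) and
    quantification cycle (Ct) so Ct values can be anticipated from
    transcriptome data. A synthetic-data generator with known truth labels
    makes the whole workflow testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
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
RoxygenNote: 7.3.3
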