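Package: aicmax
Title: Information-Content Maximization for Molecular Fingerprint Reduction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects maximally informative subsets of binary molecular
    fingerprint bits by greedily maximizing the mutual information between a
    bit group and an activity label, normalized by the label's Shannon
    entropy (the AIC-MAX criterion). Supports single-target selection,
    all-pairs ligand-selectivity selection with union/core bit summaries,
    activity labelling from potency tables, substructure-key fingerprint
    computation via SMARTS dictionaries, a synthetic-data generator with
    planted ground truth, and an evaluation harness comparing raw versus
    reduced representations by Matthews correlation coefficient with a
    Wilcoxon signed-rank test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    withr,
    ranger,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ChemmineR,
    ChemmineOB,
    optparse,
    yaml
Config/testthat/edition: 3
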