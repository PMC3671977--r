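Package: specount
Title: Spectral-Count Quantification and Threshold-Based Differential
    Expression for Label-Free Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Normalized spectral counting for label-free shotgun proteomics
    with threshold-based differential-expression calling against a baseline
    group. Implements per-replicate spectral-count normalization, group-level
    NSC summaries, fold-ratio calling with configurable cutoffs, abundance and
    presence categorization (significant, low-abundant, common, unique), Venn
    partitioning of differentially expressed proteins, and multi-label
    functional-distribution profiling of protein sets. Ships a transcribed
    35-protein seminal-plasma reference catalog with its published
    classification, a constraint-guided generator that reconstructs count
    matrices consistent with that classification, and a negative-binomial
    simulator with planted effects for operating-characteristic studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
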