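Package: tscog
Title: Quality Control and Analysis of Rodent Touchscreen Cognitive Testing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for high-throughput rodent touchscreen cognitive phenotyping
    pipelines covering the five-choice serial reaction time task (5-CSRTT),
    pairwise visual discrimination (PD) and paired-associates learning (PAL).
    Parses per-session XML event logs, applies automated quality control
    (duplicate, wrong-ID and incomplete-session rules) with a one-sided
    Q3 + k*IQR extreme-outlier filter on temporal features, computes the
    standard behavioural measures (accuracy, omissions, premature and
    perseverative responding, response latencies) with probe-pair, vigilance
    block and session-bin aggregation, runs split-plot (mixed-design) ANOVAs
    with Bonferroni post-hoc comparisons and impairment/facilitation effect
    calls, groups longitudinal multivariate trajectories into high/mid/low
    performers by seeded k-means, compares group membership by genotype with
    Fisher's exact test under Benjamini-Hochberg correction, and simulates
    synthetic cohorts with known ground truth and injectable data defects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xml2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
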