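Package: medseqr
Title: Methylation-Marker Discovery and Blood-Based Diagnostic Evaluation
    for Restriction-Enzyme Methylation Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing LpnPI-based methylated-DNA sequencing
    (MeD-seq) experiments and downstream diagnostic marker panels: read
    filtering by restriction-site position, per-site read counting, RPM
    normalisation, sliding-run chi-square calling of differentially
    methylated regions (DMRs) with Bonferroni control, cumulative DNA
    methylation scores from per-DMR ROC thresholds, qMSP 2^-dCt
    quantification with percentile positivity calls, ASAP risk scoring,
    and combined logistic classifiers evaluated by AUC and sensitivity
    at fixed specificity. Includes a synthetic-data generator for toy
    genomes, two-group site-count matrices with planted DMRs, cell-free
    DNA tumor-fraction mixtures, qMSP tables and clinical cohorts, so
    the full tissue-discovery to blood-evaluation workflow runs without
    external data.
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
    pROC,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vctrs
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
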