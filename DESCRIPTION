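Package: methdet
Title: Simulation and Analysis of Methylation-Sensitive Restriction
    Enzyme Microarrays for Relapse Prognosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for CpG-island promoter methylation
    profiling on two-colour methylation-sensitive restriction enzyme
    microarrays (MethDet-style designs with triplicate 8x8 subarrays).
    Provides a calibrated synthetic-cohort generator with known ground
    truth, GenePix-dialect import/export, spot-level quality filtering,
    lowess (MA) normalization, per-gene summarization and binary
    methylation calls, two-group differential screening with fold-change
    and p-value cutoffs, cross-validated comparison of six classifier
    families, partial-least-squares panel selection by VIP score,
    sensitivity/specificity/PPV/NPV/AUC panel evaluation, hierarchical
    clustering concordance with outcome, and noncentral-t power analysis
    with Welch-Satterthwaite degrees of freedom.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    class,
    dplyr,
    generics,
    ggplot2,
    MASS,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    mixOmics,
    pROC,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
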