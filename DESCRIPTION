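Package: enteroshift
Title: Enterotype Stability and Probiotic Response Analysis for
    Genus-Level Microbiome Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for enterotyping genus-level 16S read-count tables and
    quantifying probiotic-mediated community shifts.  Implements marker-panel
    construction with outlier masking and renormalized percentages,
    Jensen-Shannon distance with partition-around-medoids clustering,
    Calinski-Harabasz cluster-number scans, silhouette-based cluster-stability
    voting over pooled time-point combinations, a paired fold-change-ratio
    Z-statistic for probiotic response with volcano and concordance summaries,
    Shannon diversity and group comparisons, stepwise representative-taxon
    selection with a normalizing sector, and a Dirichlet-multinomial cohort
    simulator with planted enterotypes and dose-dependent effects for
    method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
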