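Package: ratconnectome
Title: Structural and Functional Brain Connectomics for Rodent MRI Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and analyses rodent brain networks from tractography-derived
    streamline records and regional resting-state time series. Structural
    connectomes are weighted by mean fractional anisotropy or by fiber density
    (the volume-normalised sum of inverse streamline lengths); functional
    connectomes use Fisher z-transformed partial correlations with negative
    correlations excluded. Graph-theoretical characterisation covers degree,
    strength, global and nodal efficiency, and binary and weighted clustering.
    Group comparison combines Kruskal-Wallis rank tests with an age-adjusted
    Gaussian generalized linear model and Benjamini-Hochberg false discovery
    rate correction over regions, and network metrics are screened against
    behavioral outcomes with Spearman correlations. A synthetic two-group
    cohort generator with planted effects makes every stage testable without
    imaging data, and a configuration-driven pipeline runs the full analysis
    end to end.
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
    utils,
    withr,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
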