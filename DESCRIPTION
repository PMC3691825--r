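Package: binstates
Title: Binary-State Profiling of Gene Expression Along Tumor Progression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies genes whose expression follows oncogene-, tumor-
    suppressor- or metastasis-suppressor-like activation patterns across
    ordered tumor-progression stages.  Expression is discretized per sample
    into active/uncertain/inactive states using a cutoff and an uncertainty
    band, aggregated into per-stage states by a minimum-proportion rule, and
    concatenated into stage-state profiles.  Profiles are scored with
    empirical p-values from a stage-label permutation null and selected by
    false discovery rate.  Includes exhaustive grid-search estimation of the
    discretization parameters against random uniform datasets, a synthetic
    data generator with ground-truth progression profiles for benchmarking,
    and reference implementations of common differential-expression
    selectors (stage-versus-rest t and Wilcoxon tests, across-stage F test,
    quantile-based outlier scores) for method comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
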