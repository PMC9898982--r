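Package: epiren
Title: Integrative Analysis of Epigenetically Enhanced Adhesion-Gene
    Expression in Multiple Myeloma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative pipeline for studying how adhesion-related genes
    (integrins such as ITGB7, non-integrin adhesion molecules, and the
    co-stimulatory genes CD28/CD86) become overexpressed in molecular
    subgroups of plasma-cell neoplasia across the MGUS, SMM and MM stages.
    Provides stage- and subgroup-aware differential-expression screening of
    log2 microarray intensities (Mann-Whitney tests plus z-score filters on
    group medians), summarisation of CpG methylation into differentially
    methylated regions with methylation-expression correlation, interval
    overlap statistics between DMRs and histone-mark peak sets, a rule-based
    classifier of bivalent / active-enhancer / super-enhancer chromatin
    states with CTCF-window detection, and quantitative readouts of
    perturbation assays (per-CpG pyrosequencing deltas with two-way ANOVA,
    delta-delta-Ct qPCR fold changes, four-parameter log-logistic IC50
    fits). A deterministic synthetic-cohort generator with planted ground
    truth makes every stage testable end to end without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    stringr,
    stats,
    utils,
    ggplot2,
    generics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
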