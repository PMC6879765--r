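Package: xdisparity
Title: Sex Disparity in the Expression of X-Linked Somatic Mutations in Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying cancer sex disparity through the lens of
    the p53/X-chromosome axis: the RNA-mutated allele frequency (RMAF) of
    somatic exome mutations with non-expressed/expressed mutation (NEM/EM)
    classification, integration of population cancer-registry incidence with
    cohort TP53 mutation frequencies into per-100,000 mutant-cancer rates by
    sex, propensity-score matching weights with an iterative covariate-balance
    loop, per-gene weighted chi-squared NEM tests with signed chi-scores,
    Poisson log-linear mutation-burden models, logit-scale RMAF sex
    comparisons, and Kaplan-Meier/log-rank survival stratification. Includes a
    synthetic-cohort generator emulating X-inactivation so the whole pipeline
    is testable without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    withr
Suggests:
    edgeR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
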