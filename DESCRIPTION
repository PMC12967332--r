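Package: fishnetr
Title: Network-Module Gene Prioritization from Gene-Level Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prioritizes genes from gene-level association P-values by finding
    network modules enriched for low P-values (rank-based chi-squared scoring
    with Bonferroni control), requiring member genes to share an over-represented
    functional annotation (hypergeometric test with Benjamini-Hochberg control
    and greedy redundancy reduction), and validating the resulting candidate set
    with a permutation-based empirical false discovery rate and quantile test.
    Includes a rank-reversal diagnostic for detecting dependency between the
    summary statistics and the module structure, discovery/replication
    evaluation, synthetic data generators with planted signal, and a small
    command-line interface.
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
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
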