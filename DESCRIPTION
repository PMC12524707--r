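Package: gmtrepurpose
Title: Transcriptomic Drug Repurposing Against Glial-Mesenchymal Transition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives a glial-mesenchymal-transition (GMT) gene signature from
    glioblastoma expression cohorts via single-sample gene-set enrichment,
    weighted co-expression modules, negative-binomial differential expression
    and multi-metric network-centrality hub ranking, then ranks small molecules
    that reverse the signature with connectivity-map scoring (weighted
    Kolmogorov-Smirnov statistic, normalized connectivity score, tau
    percentile) and a multi-criterion drug funnel (blood-brain-barrier
    permeability, P-glycoprotein substrate consensus, literature co-occurrence,
    Tanimoto structural similarity). Includes seeded synthetic-data generators
    that emulate the statistical structure of the cohorts so every stage is
    testable without external downloads, plus survival screening (Kaplan-Meier,
    log-rank, univariate Cox) for prognosis-related genes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
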