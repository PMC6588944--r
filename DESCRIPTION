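Package: tcrpersist
Title: Longitudinal T Cell Receptor Repertoire Analysis and Persistent
    Receptor Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing longitudinal TCR beta-chain immunosequencing
    data: reading immunoSEQ-style clonotype exports, repertoire summary
    statistics (Jaccard overlap, Shannon diversity, clonality, V/J usage,
    rarefaction), identification and profiling of receptors that persist
    across all time points of an individual's series, CDR3 amino-acid
    similarity networks with permutation tests linking connectivity to
    persistence, detection of clonal cohorts with correlated temporal
    trajectories via correlation graphs and maximal cliques, and enrichment
    of persistent receptors among receptors shared widely ("public") across
    an external cohort. Includes a synthetic longitudinal repertoire
    generator with known ground truth so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
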