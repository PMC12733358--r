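Package: rpsig
Title: Ribosomal Protein mRNA Signature Discovery in Cancer Expression Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects subtype-specific ribosomal-protein (RP) mRNA signatures in
    gene-expression cohorts. Provides RP-restricted compositional normalization
    of counts, FPKM or microarray intensities; a pairwise sample distance that
    sums absolute log2 fold changes over RP genes; exact t-SNE embedding of the
    precomputed distance with density-based cluster extraction; independent
    cluster validation with a hexagonal self-organizing map and majority-rule
    node coloring; per-RP differential expression (median log2 fold changes and
    Wilcoxon rank-sum tests); and cluster-versus-clinical statistics (Fisher's
    exact tests, Kaplan-Meier estimates with not-reached medians, log-rank and
    multivariate Cox proportional-hazards models). A seeded synthetic cohort
    generator with planted RP signatures, survival hazards and clinical markers
    supports end-to-end testing without access to patient data.
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
    grDevices,
    jsonlite,
    mclust,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    cluster,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
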