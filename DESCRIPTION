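Package: survsig
Title: Prognostic Gene-Signature Discovery and Risk Stratification for
    Survival Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovers prognostic gene-expression signatures from
    right-censored survival cohorts and turns them into a simple,
    transferable risk classifier.  The pipeline filters dim and flat
    genes, screens candidates by univariate Cox proportional-hazards
    regression, grows a multigene model by robust likelihood-based
    forward selection (held-out partial log-likelihood averaged over
    random train/validation partitions, AIC stopping) with subsample
    stability counting, assigns each signature gene a positive or
    negative prognostic direction, and classifies patients by the
    number of genes in their adverse state relative to the cohort
    median (the "at least k active genes" rule), including a log-rank
    threshold sweep and frozen-model validation on an independent
    cohort.  A synthetic-cohort generator with a planted signature
    makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    survival,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
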