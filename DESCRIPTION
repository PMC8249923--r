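Package: secretoscope
Title: Surprisal Analysis of Tumor Explant Secretomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Decomposes cytokine and chemokine concentration matrices from
    tumor explant cultures into a steady-state term plus a small number of
    unbalanced co-secretion processes via singular value decomposition of
    log concentrations (surprisal analysis). Provides iterative-SVD
    imputation of missing multiplex measurements, Monte-Carlo significance
    calls for the number of processes, fold-over-baseline cytokine
    membership and per-sample activity calls, Pearson correlation of
    process amplitudes with immune-infiltrate composition, principal
    component analysis of treatment profiles, per-cytokine treatment
    comparisons, signed functional subnetworks from user-supplied edge
    lists, and a seeded synthetic-data generator with planted processes
    for parameter-recovery benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
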