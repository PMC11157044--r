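Package: mlfcn
Title: Spatio-Temporal Multilayer Functional Connectivity Networks and
    Dynamic Rich-Club Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Constructs whole-brain spatio-temporal multilayer functional
    connectivity networks from ROI-level BOLD time series: a hypergraph
    layer over macroscale resting-state networks estimated by L1-regularized
    (lasso) regression, a within-network gray-matter adjacency layer, and a
    white-matter to gray-matter adjacency layer, repeated over sliding time
    windows. Provides four dynamic rich-club metrics (temporal centrality,
    temporal stability, local functionality, joint functionality) computed
    from per-window core-node assignments, plus test-retest reliability
    analysis via the intraclass correlation coefficient and group contrasts
    via independent-samples t-tests with false discovery rate correction.
    Includes a seeded synthetic-cohort generator with planted hub structure,
    regime switching, group effects and paired sessions, and an end-to-end
    pipeline runner with a command-line wrapper.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    RNifti,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
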