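Package: agephase
Title: Multi-Omics Discovery and Characterization of Latent Aging Phases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Integrates transcriptome and methylome profiles into a fused
    subject-similarity network (similarity network fusion), discovers latent
    aging phases by spectral clustering with eigen-gap model selection,
    validates them with linear molecular-age clocks and an interquartile-range
    outlier rule, scores gene sets by cross-validated random-forest
    "predictivity" to reconstruct the succession of aging hallmarks, and
    quantifies the late-life loss of pathway signal and rise in transcriptional
    noise. Ships a synthetic multi-omics cohort generator with ground-truth
    phases so every stage of the pipeline can be tested against known
    structure. Results are tidy tibbles with tidy(), glance() and autoplot()
    methods.
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
    mclust,
    purrr,
    randomForest,
    rlang,
    stats,
    sva,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
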