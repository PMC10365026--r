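Package: tfsig
Title: Integrative Derivation of Transcription-Factor-Driven Oncogenic Gene Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives a transcription-factor-driven oncogenic gene signature by
    integrating cohort expression data, knockdown experiments and ChIP-seq
    regulatory landscapes. Implements anchor-gene correlation, a defined
    differential-expression engine (median-of-ratios normalization, Welch t,
    Benjamini-Hochberg), sign-concordant overlap and knockdown-concordance
    filtering, replicate-consensus peak derivation with GREAT-style
    basal-plus-extension regulatory domains, ROSE-style super-enhancer
    stitching and rank cutpoint calling, k-means chromatin-state
    classification of bound sites, and survival stratification by maximally
    selected rank statistics. Ships a synthetic-data generator that plants
    ground truth (coupled targets, knockdown responses, super-enhancers,
    chromatin states, survival effects) so every stage carries a recovery
    test, plus a configuration-driven pipeline with deterministic seeding and
    run manifests.
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
    jsonlite,
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
    mclust,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
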