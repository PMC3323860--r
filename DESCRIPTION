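Package: mimofilter
Title: Multiple-Output Causal Feature Selection by Interaction Information
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-selection feature ranking for classification problems
    with several binary outcomes, combining univariate Gaussian-approximation
    mutual information with a multi-target interaction-information causal
    score so that direct causes of a latent disease variable are prioritized
    over mere effects. Includes a linear-Gaussian causal-network simulator
    for benchmarking cause prioritization, a Gaussian naive Bayes evaluation
    harness (AUC, RMSE, SAR, F, McNemar and Wilcoxon comparisons with Holm
    correction), and meta-analytic holdout and leave-one-dataset-out
    validation protocols that pool correlations across studies with the
    Fisher z transform.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
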