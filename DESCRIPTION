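Package: growthbayes
Title: Bayesian Comparison of Bacterial Growth Rates via Nested Sampling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fits the Baranyi-Roberts model to bacterial growth curves by
    nested sampling, returning the model evidence together with weighted
    posterior samples, and detects differences in the maximum specific
    growth rate between pairs of curves by Bayes factors on Jeffreys'
    scale. Supports censored (below-detection) observations, an inferred
    or prescribed noise level, and informative Gaussian or Cauchy priors
    on the growth rate built from clusters of previously analysed curves
    via the law of total variance. A frequentist F-test baseline and
    simulation drivers for power/detection studies are included.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
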