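Package: envsca
Title: Spectral Envelope and Optimal Scaling Classification of Categorical Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Supervised classification of categorical time series using
    frequency-domain features. Each series is indicator-encoded against a
    reference category, its spectral matrix is estimated by a smoothed
    periodogram, and the spectral envelope (largest eigenvalue of the real
    part of the spectral matrix) together with the optimal scalings (the
    associated unit eigenvector) are used as low-dimensional, interpretable
    features. Three distance-based classifiers are provided: envelope-only,
    scalings-only, and an adaptive convex combination whose mixing weight is
    tuned by leave-one-out cross-validation. Spectral-matrix-based baseline
    classifiers (total variation, Kullback-Leibler, and Chernoff disparities),
    a lag-1 multinomial-logit simulator with study presets, a Monte-Carlo
    study driver, variable-length series support via periodogram
    interpolation, and synthetic hypnogram generation are included.
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
    tidyr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
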