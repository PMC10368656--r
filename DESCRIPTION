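Package: aquascene
Title: Spatiotemporal Visual Statistics of Aquatic and Terrestrial Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the visual statistics of natural habitat
    video, with an emphasis on comparing aquatic and terrestrial scenes.
    Computes global and locally-normalized (difference-of-Gaussians) contrast
    fields, their distributional moments and Shannon entropy, hemifield
    (upper versus lower visual field) summaries, windowed three-dimensional
    spatiotemporal power spectra with log-spaced ring binning and log-log
    slope fits, Laughlin-style cumulative-distribution response
    nonlinearities with response-entropy analysis, and a Snell's-law
    refraction correction for through-water visual stimulus geometry.
    Includes synthetic video generators with known ground-truth statistics
    (power-law spectra, skewed intensity fields, illumination gradients,
    moving-dot fields) so the full pipeline can be exercised and validated
    without field recordings, plus the inferential layer (pooled t-tests with
    d-prime, 2x2 ANOVA with partial eta-squared and Tukey-Kramer follow-ups)
    used to compare environments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
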