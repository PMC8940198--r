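Package: upsens
Title: Unpredictability of Caregiver Sensory Signals and Longitudinal
    Cohort Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies the unpredictability of caregiver sensory signals
    (auditory, visual, tactile) during caregiver-child interaction as the
    entropy rate of a first-order Markov process over the eight
    presence/absence combinations of the three modalities.  Parses
    interval-coded behavioural event logs into state sequences, estimates
    transition models and entropy rates, simulates calibrated synthetic
    cohorts of dyads with planted longitudinal moments, fits two-class
    linear latent growth mixture models to repeated symptom scores by EM,
    and reproduces a cohort-level analysis pipeline (stability tests,
    cross-construct correlations, trajectory-class comparisons and
    covariate-adjusted linear models).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    MASS
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
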