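Package: firescape
Title: Frequency-Ratio Fire Susceptibility Mapping and Matching-Based
    Protection Effect Estimation
Version: 0.1.0
Authors@R:
    person("firescape", "developers", email = "firescape@example.org",
           role = c("aut", "cre"))
Description: Tools for landscape-scale vegetation fire analysis on a
    harmonized equal-area grid. Implements frequency-ratio susceptibility
    mapping (per-class frequency ratios for causative factors, the summed
    fire susceptibility index, and causative-factor ranking within
    high-susceptibility pixels, stratified by protection status) and
    Mahalanobis-distance matching with replacement and a caliper to
    estimate the average treatment effect of protected-area status on
    fire occurrence, with covariate balance diagnostics and a correlation
    screen. Includes grid harmonization utilities (majority-filter and
    cubic-convolution resampling, proportional allocation, Horn slope and
    aspect, Euclidean distance layers, active-fire CSV rasterization) and
    a synthetic landscape generator with closed-form counterfactual ground
    truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
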