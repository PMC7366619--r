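Package: phantomech
Title: Mechanical Characterization of Soft Silicone Mixtures for Organ Phantoms
Version: 0.1.0
Authors@R: person("Phantomech", "Developers", role = c("aut", "cre"),
    email = "maintainers@phantomech.dev")
Description: A two-stage analysis pipeline for characterizing soft silicone
    mixtures against elastic targets for anatomical organ phantoms (human
    kidney cortex). Stage one estimates low-strain (E1, toe) and high-strain
    (E2, post-heel) compressive moduli from pooled uniaxial-compression
    stress-strain records by segmented linear regression with three change
    points, using iterative linearization with bootstrap restarting and
    seed-averaged estimates. Stage two fits the two-parameter Blatz
    hyperelastic constitutive model (alpha, gamma) to each technical
    replicate by nonlinear least squares and aggregates replicates into
    means, standard deviations and quantiles. Includes plain-text
    stress-strain I/O, preprocessing (common truncation, stretch-ratio
    conversion, replicate pooling), a synthetic-data generator with known
    ground truth for recovery testing, and screening of mixtures against
    target compressive moduli of 20 kPa (low strain) and 500 kPa
    (high strain).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
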