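Package: dfcomp
Title: Connectionist Simulation of Decimal-Fraction Magnitude Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates two-choice magnitude comparison of decimal fractions
    with a componential connectionist model: place-coded single-digit
    comparison networks trained by the delta rule, a broadly tuned
    number-of-digits comparison network, and a cognitive-control layer with
    conflict monitoring and Hebbian adaptation of task-demand weights.
    Includes a constrained stimulus generator for matched decimal-fraction
    pairs, a simulated-experiment runner with per-participant noise and
    trial order, and repeated-measures analyses (Greenhouse-Geisser
    corrected ANOVA, paired tests, arcsine-transformed error rates) of the
    simulated response times and error rates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    car,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
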