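Package: vertigopop
Title: Stage-Structured Seasonal Population Dynamics of Vertigo
    moulinsiana Under Snow-Cover Loss
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Deterministic, discrete-time, age-structured population model
    for the land snail Vertigo moulinsiana, with five life stages (eggs,
    juveniles and three adult age classes) on a six-month May-October
    activity calendar and a single aggregated overwintering transition.
    Converts winter minimum air temperature and a supercooling-point (SCP)
    distribution into freeze mortality and an adjusted winter-survival
    parameter, runs snow-cover-disappearance scenarios over multiple
    seasons, and summarises them (final-season statistics, time to
    quasi-extinction, seasonal growth rate). Includes a stochastic
    individual-based simulator for cross-validating the deterministic
    core, seeded synthetic fixtures (parameter sets and calibrated SCP
    samples), one-at-a-time sensitivity analysis, YAML configuration and
    CSV/JSON input-output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
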