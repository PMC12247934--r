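Package: vasomyo
Title: Pressure Myography Simulation and Analysis for Vascular Mechanics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for ex-vivo pressure myography of native and
    tissue-engineered blood vessels. Synthesizes pulsatile and stepwise
    intraluminal pressure protocols, forward-simulates vessel
    pressure-diameter behavior with a four-fiber-family hyperelastic wall
    model under incompressible thin-wall equilibrium, renders and tracks
    vessel diameters on grayscale frames, and analyzes recordings for
    pulse statistics, FFT pulse frequency, dynamic compliance, burst
    pressure, plateau pressure, and vasoreactivity normalization.
    Includes nonlinear least-squares fitting of the constitutive
    parameters to pressure-diameter data and linearized material
    stiffness at loaded states.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    png,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
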