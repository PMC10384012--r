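Package: osteomill
Title: Mechanistic Cutting-Force Simulation for Vibration-Assisted
    Micro-Milling of Bone
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates instantaneous cutting forces in two-dimensional
    vibration-assisted micro-milling of anisotropic cortical bone. Combines
    direction-dependent shear strength and friction of cortical bone with
    oblique-cutting (Armarego) shear coefficients, slip-line ploughing with an
    edge-radius equivalent rake angle, trochoidal tool-tip kinematics including
    tool runout and 2D platform vibration, an implicit instantaneous uncut
    chip-thickness solver, and axial flute integration to Fx/Fy/Fz force
    traces. Includes a single-factor experiment grid, zero-phase low-pass
    filtering, RMS summaries, parameter sweeps, and synthetic dynamometer
    traces for offline model-experiment comparison.
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
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
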