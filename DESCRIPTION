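Package: bposim
Title: Geometric Simulation and Planning of Bilateral Pelvic Opening-Wedge Osteotomy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models bilateral pelvic opening-wedge osteotomy (BPO) as a rigid
    sagittal-plane rotation of the cranial pelvic fragment about a fulcrum at the
    sciatic notch. Predicts spinopelvic sagittal alignment parameters (sagittal
    vertical axis, pelvic incidence, pelvic tilt, sacral slope, T1 pelvic angle,
    T1 spinopelvic inclination) as functions of the osteotomy opening angle, both
    by direct landmark rotation and by closed-form trigonometric equations in
    patient-specific distances and angles. Includes a constraint-based planner
    for the feasible opening-angle range under standard sagittal-balance
    criteria, a law-of-cosines stretch-ratio model for muscles crossing the
    osteotomy site, and a synthetic-patient generator that constructs landmark
    sets realizing prescribed baseline alignment.
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
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
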