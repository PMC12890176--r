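Package: rciburn
Title: Compartmental Model of Thermal Burn Combined with Local Irradiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Mechanistic two-compartment ordinary-differential-equation model
    of the innate immune response to a superficial thermal burn combined with
    a prompt, locally confined dose of ionizing radiation. The package
    provides the full 16-state model (neutrophils, M1/M2 macrophages,
    pro- and anti-inflammatory T lymphocytes, fibroblasts, damage, debris and
    pathogen across a wound and a surrounding irradiated-tissue compartment),
    dose-dependent initial conditions built from linear-quadratic cell
    survival curves and a piecewise thermal-fluence-to-damage map, a stiff
    ODE simulator with healing-event detection, linear-quadratic survival
    curve fitting, a Latin-hypercube feasibility-sampling pipeline with
    representative-set selection, and a multi-test extended FAST (MeFAST)
    global sensitivity screen with estimate/fix parameter classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    lhs,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
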