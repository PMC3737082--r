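Package: fdgkin
Title: Two-Tissue-Compartment FDG Kinetic Modeling and Protocol Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Compartmental analysis of dynamic FDG PET data in small animals.
    Implements the two-tissue-compartment model with a fractional blood volume
    term, estimation of the rate constants K1-k4 by bounded nonlinear least
    squares, the macro-parameters K(FDG) and CMRglc, plasma input-function
    derivation from whole-blood activity with several blood-cell-uptake
    corrections, tri-exponential modeling of infusion-shaped input functions,
    and a simulation framework quantifying how blood volume assumptions,
    timing and calibration errors, data smoothing, the blood-cell correction,
    and the administration protocol and blood sampling interval distort the
    estimated kinetic parameters.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
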