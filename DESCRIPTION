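Package: kalmanspec
Title: Kalman Filter Spectral Unmixing and Assay Validation for
    Overlapping UV-Vis Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Sequential Kalman-filter estimation of multiple analyte
    concentrations from a single overlapping UV-Vis absorption spectrum
    under the Beer-Lambert linear mixture model, with a classical
    least-squares oracle for verification. Includes the standard assay
    validation calculus for pharmaceutical analysis (relative error,
    repeatability against the half-Horwitz criterion, LOD/LOQ, spike
    recovery, tablet content, and two-method F/t equivalence testing), a
    Gaussian-band synthetic spectrum generator emulating the
    hydrochlorothiazide/losartan two-component system, and a command-line
    interface binding the workflow together.
License: MIT + file LICENSE
Encoding: UTF-8
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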