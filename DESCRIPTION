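Package: opperg
Title: Modeling Retinal Function, Blood Flow and Oxygen Extraction Under
    Ocular Perfusion Pressure Challenge
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative model coupling ocular blood flow, oxygen
    extraction ratio (OER) and intraocular-pressure (IOP) mechanical
    stress to retinal function (electroretinogram b-wave amplitude)
    during acute ocular perfusion pressure (OPP) challenge.  Provides
    the four-parameter forward model (exponential OER-flow law, two-line
    mechanical-stress hinge), multi-start sum-of-squares parameter
    fitting, case- and residual-resampling bootstrap confidence
    intervals, chi-square goodness-of-fit grading, derivation of
    putative OER and mechanical stress from simultaneous oxygen-tension,
    flow and function measurements, and a synthetic cohort generator
    emulating the IOP staircase protocol with an autoregulatory
    flow-OPP curve.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    lhs,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
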