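Package: ohcacover
Title: Ambulance Delay Zones and Public AED Placement for
    Out-of-Hospital Cardiac Arrest
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing emergency medical service response times
    to out-of-hospital cardiac arrest (OHCA) and for planning public
    placement of automated external defibrillators (AEDs). Provides a
    seeded synthetic-city event generator, cohort descriptives with the
    standard inclusion filter, raster isochrone service areas from
    ambulance bases, a Bayesian spatial survival model of response time
    with right-censoring at 300 s yielding per-cell posterior exceedance
    probabilities and a diurnal relative-risk curve via harmonic
    covariates, greedy and exact solvers for the maximal covering
    location problem (MCLP) with coverage-versus-p curves, a paired
    Wilcoxon signed-rank comparison of bystander AED versus ambulance
    times, and an end-to-end reproducible pipeline with a run manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    splines,
    stats,
    tools,
    utils
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
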