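Package: mrflow
Title: Instantaneous Mitral Regurgitant Rate from Cardiovascular MR Flow and Volume Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the instantaneous mitral regurgitant rate from
    cardiovascular magnetic resonance derived data as the pointwise
    difference between the rate of blood exiting the left ventricle
    (the slope of the left ventricular volume curve) and the rate of
    blood arriving in the proximal aorta (the phase-contrast flow
    curve). Provides through-plane velocity-map flow quantification
    with stationary-phantom baseline correction, left ventricular
    volumetry by Simpson summation of endocardial contours, partition
    of systole into equal early/mid/late thirds, per-third peak and
    mean regurgitant rates, the peak-to-average regurgitant rate
    ratio, regurgitant-volume severity grading, jet-pattern
    classification, and a forward simulator that generates velocity
    maps, contour stacks, phantom series and jet-presence data with
    known ground truth so the whole chain is testable without scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
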