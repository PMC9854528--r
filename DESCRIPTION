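Package: avprosody
Title: Audiovisual Prosody: Sinusoidal Pitch Contours Around Brow Raises
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for the temporal coordination of eyebrow
    movement and intonation in conversational video. From frame-level facial
    landmark measurements and pitch tracks sampled at 30 fps, the package
    locates the eyebrow peak of each subtitle-defined segment, extracts a
    121-position analysis window around it, fits a four-parameter
    baseline-shifted sinusoid to the pre- and post-peak pitch contours by
    multi-start nonlinear least squares, categorizes contour phases, and
    models brow-peak magnitude from the sinusoid parameters with
    speaker-level random intercepts. A synthetic-data generator produces
    frame-level corpora with known coupling coefficients for end-to-end
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    mgcv,
    stats,
    tools,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
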