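Package: ftirgait
Title: Quantitative Gait Analysis from fTIR Walkway Videos of Rodents
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tracks the body and footprints of a rodent walking over a
    frustrated-total-internal-reflection (fTIR) walkway filmed from below,
    and derives a comprehensive set of quantitative gait parameters:
    per-pixel median background modelling, body/footprint segmentation and
    body-axis decomposition (nose, head, centre, back point, tail points),
    footprint blob linking into stance events with leg identification,
    step-cycle timing (stance/swing time, period, duty factor, step length,
    swing speed), body-frame stance traces with anterior and posterior
    extreme positions, footprint clustering and stance linearity indexes,
    leg-combination gait categories, contralateral phase estimation by
    circular statistics, tail kinematics and relative footprint pressure.
    A fully ground-truthed synthetic trial generator renders fTIR-like
    frame sequences so the entire pipeline can be validated end to end
    without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    generics,
    yaml,
    png,
    tiff,
    EBImage,
    minpack.lm,
    stats,
    utils,
    grDevices,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
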