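Package: spiraltremor
Title: Wearable-Sensor Quantification of Essential Tremor During Spiral
    Drawing
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Quantifies essential-tremor severity from wearable triaxial
    accelerometers and a digitizing tablet recorded while a subject draws
    an Archimedes spiral.  Computes the orientation-invariant acceleration
    vector magnitude, applies a zero-phase 0.5 Hz high-pass filter, and
    derives the 4-12 Hz : 0.5-4 Hz power-spectral-density band-power
    ratio together with the pen-down task time; estimates
    Fahn-Tolosa-Marin (FTM) severity scores by ordinary least squares;
    compares groups with nonparametric tests; classifies tremor phenotype
    with leave-one-out cross-validated support vector machines; and
    simulates complete synthetic spiral-drawing cohorts so the whole
    pipeline can be exercised without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    e1071,
    graphics,
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
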