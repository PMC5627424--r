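Package: thermofoot
Title: Plantar Thermogram Analysis for Early Indication of Diabetic Foot Ulcers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing radiometric plantar thermograms acquired with
    low-cost mobile thermal cameras. Segments the plantar feet from a cold
    homogeneous background by Otsu histogram-shape thresholding followed by a
    binary smoothing chain (border clearing, diamond erosion, hole filling),
    then flags hyperthermic regions - local skin-temperature elevations of at
    least 2.2 degrees Celsius, an established early indicator of neuropathic
    foot ulceration - by two independent techniques: a second-stage Otsu
    mean-difference with a Welch t-test, and a contralateral point-to-point
    temperature difference with mirroring, intensity-based rigid registration
    and Sobel edge exclusion. Includes a synthetic phantom generator that
    emulates the acquisition protocol (160 x 120 grids, 0.1 degree sensor
    noise, heated-object hotspots of standard shapes) with ground-truth masks,
    plus plain-text matrix I/O and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    png,
    tiff,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
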