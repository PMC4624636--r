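Package: pamoxi
Title: Photoacoustic Mammography Simulation, Oximetry and Microvessel Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for dual-wavelength photoacoustic
    mammography (PAM). Generates digital breast phantoms with vascular and
    lesion structures, simulates dual-sided 756/797 nm illumination and
    detection by a planar ultrasound array, reconstructs initial-pressure
    volumes by universal back projection, unmixes oxy- and deoxyhemoglobin to
    map oxygen saturation (SO2), and summarizes regions of interest. A
    companion histomorphometry module quantifies microvessels on synthetic
    CD31-stained slides via HSI thresholding, Crofton perimeter estimation and
    block-wise total vessel perimeter (TVP) maps, and a cohort-statistics
    module provides the nonparametric tests and visibility accounting used in
    clinical PAM studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    jsonlite,
    yaml,
    EBImage,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    tiff,
    png
Config/testthat/edition: 3
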