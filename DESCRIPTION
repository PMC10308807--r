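Package: dropwet
Title: Sessile-Droplet Wetting, Evaporation and Forced-Wetting Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for sessile-droplet goniometry of
    bacteria-laden suspensions: numerical solution of the axisymmetric
    Young-Laplace equation, contour and contact-angle extraction from
    side-view images, droplet volume estimation by profile fitting,
    evaporation kinetics (linear volume decay, contact-line depinning),
    centrifugal forced-wetting event detection with tangential Bond
    number and Furmidge retention-force quantification, power-law
    rheology fitting, and live/dead cell counting by watershed
    segmentation. Includes a synthetic-data generator producing every
    input the pipeline consumes, with exact ground truth, so that all
    stages are testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    EBImage,
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
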