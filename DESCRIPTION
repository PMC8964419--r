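Package: strandlogic
Title: Kinetic Modeling and Design of Cell-Free Biosensor Strand-Displacement Circuits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Compiles declarative descriptions of cell-free biosensor circuits
    that couple allosteric-transcription-factor-regulated T7 transcription to
    toehold-mediated DNA strand displacement (TMSD) into mass-action reaction
    networks, simulates fluorescence time courses by ODE integration, evaluates
    molecular logic truth tables (NOT, OR, AND, NOR, IMPLY, NIMPLY, NAND),
    designs kinetic-comparator threshold gates and thermometer-coded
    analog-to-digital converter (ADC) tube strips for semiquantitative ligand
    readout, converts plate-reader fluorescence to micromolar equivalent
    fluorescein (MEF) via calibration standards, and estimates kinetic
    parameters from time courses. Ships a library of twelve logic circuits and
    the sensor circuits they are built from, plus synthetic plate-reader data
    generators so every stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
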