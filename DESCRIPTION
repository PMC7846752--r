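Package: isomob
Title: Oxygen and Carbon Isotope Palaeomobility Analysis for Tooth Enamel Carbonate
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying non-local individuals in prehistoric
    communities from the oxygen and carbon isotope composition of tooth
    enamel carbonate. Provides the standard V-PDB to V-SMOW scale
    conversion and an enamel-carbonate-to-drinking-water transfer
    function, per-community descriptive and robust statistics (MAD
    variants, IQR), a multi-criterion locality screen for outlier
    ("newcomer") detection with consensus reporting, reference-water
    compatibility checks, breastfeeding and diagenetic-mixing screens,
    and a seedable synthetic cemetery generator with planted migrants
    for power and false-positive evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
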