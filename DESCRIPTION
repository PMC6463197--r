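Package: halovalid
Title: Method Validation and Measurement Uncertainty for Targeted
    GC-MS/MS Quantification of Halogenated Contaminants in Fish
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the computational side of within-laboratory
    validation of targeted multiple-reaction-monitoring (MRM)
    quantification methods for organochlorine pesticides and
    polybrominated diphenyl ethers in fish tissue.  Implements
    single-point standard-addition quantification with internal-standard
    response ratios, matrix-effect evaluation, linearity assessment via
    relative response factors, detection and quantification limits from
    replicate spikes, recovery, intra- and inter-day precision, trueness
    against certified reference materials, top-down combined
    measurement-uncertainty budgets from quality-control charts, and
    analytical Eco-Scale greenness scoring.  A seeded synthetic
    peak-area batch generator emulates spiked fish-homogenate batches
    (per-analyte response factors, matrix effects, lipid-dependent
    signal suppression, replicate noise) so the whole pipeline is
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
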