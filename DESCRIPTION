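Package: substispace
Title: Substituent Extraction, Property Estimation and Craig-Plot Navigation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Extracts organic substituents from molecule corpora by cutting
    chemically activated single bonds, estimates the Hansch-Fujita pi
    hydrophobicity parameter from Wildman-Crippen atom-contribution logP and
    a Hammett sigma-para-compatible electronic parameter from partial atomic
    charges of substituted benzene probes, classifies substituents by root
    atom and attachment environment, and supports bioisosteric
    nearest-neighbour queries, diversity selection and Craig-plot export.
    Includes a seeded synthetic-corpus generator with a long-tail substituent
    frequency structure for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
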