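Package: ahldesign
Title: Design of Orthogonal AHL Cell-to-Cell Communication Channels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterisation and design toolkit for acyl-homoserine lactone
    (AHL) based cell-to-cell communication in synthetic microbial consortia.
    Fits four-parameter logistic transfer functions to receiver-device
    titration data with a fixed basal constraint, maintains a complete
    device-by-inducer chemical-crosstalk parameter database, and selects sets
    of orthogonal communication channels (device, inducer, concentration
    window) that satisfy user-defined activation and crosstalk fold-change
    constraints via an exhaustive non-attacking-rooks search. Includes a
    synthetic-data generator with planted orthogonality structure for testing
    and benchmarking, and command-line entry points for a reproducible
    fit/report/search workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
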