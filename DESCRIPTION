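Package: satmap
Title: Chemical Space Maps from Satellite-Based Similarity Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Visualizes the chemical space of a compound library by principal
    component analysis of an N x k Tanimoto fingerprint-similarity matrix
    computed against an adaptively chosen subset of "satellite" compounds,
    instead of the full N x N matrix.  Provides SDF/SMILES input with
    salt-stripping standardization, MACCS and ECFP4 fingerprints, random and
    MaxMin satellite selection, a forward procedure that grows the satellite
    set until consecutive maps agree, a backwards validation sweep against the
    full-matrix gold standard, library-diversity metrics, and synthetic
    compound-library generators for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ChemmineR,
    ChemmineOB,
    methods,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
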