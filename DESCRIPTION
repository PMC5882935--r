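Package: glycoMSn
Title: De Novo Structural Determination of Glucose Oligosaccharides by
    Sodiated MSn Spectral Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for de novo structural determination of underivatised
    glucose oligosaccharides from multi-stage collision-induced dissociation
    (CID) of sodium adducts. Implements a sodiated fragment m/z calculus in
    which dehydration and cross-ring (retro-aldol) cleavages are restricted
    to the reducing ring, the logical MSn decision procedures for
    trisaccharides, tetrasaccharides and linear pentasaccharides, an
    anomer-resolved disaccharide CID fingerprint database with cosine
    matching and weighted spectral subtraction, an ion-trap CID simulator
    that produces MSn spectral trees for known structures, and an elucidator
    that recovers linkages, anomeric configurations and branch locations
    from such trees with per-bond provenance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
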