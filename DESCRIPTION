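Package: ShapSig
Title: Shapley-Value Signatures of Dual-Target Compounds
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Explainable classification of dual-target versus single-target
    bioactive compounds. Curates ChEMBL-style bioactivity tables, encodes
    molecules as collision-free binary vectors of layered circular atom
    environments (Morgan, bond radius 2), trains balanced random forest
    classifiers with per-tree majority-class under-sampling, computes exact
    per-compound Shapley values with the path-dependent tree explainer
    (verified against brute-force coalition enumeration), and aggregates
    present/absent feature contributions into prioritized feature sets that
    are mapped back onto compound structures to reveal coherent substructure
    signatures of dual-target activity. Includes a synthetic bioactivity
    generator with planted structural motifs for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    Rcpp,
    jsonlite,
    igraph,
    ChemmineR,
    ChemmineOB
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'chem.R'
    'featurize.R'
    'synthetic.R'
    'curation.R'
    'brf.R'
    'shapley.R'
    'signatures.R'
    'pipeline.R'
    'RcppExports.R'
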