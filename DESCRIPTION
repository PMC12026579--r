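Package: pathcolor
Title: Metabolic Pathway Involvement Prediction from Atom-Color Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Predicts whether a chemical compound is involved in a metabolic
    pathway by reformulating extreme multi-label pathway classification as
    binary classification over compound-pathway pairs. Compounds are parsed
    from MDL molfiles, optionally standardized by InChI (or canonical SMILES)
    round-tripping so that tautomeric, resonance and protonation variants map
    to one representative structure, and featurized as counts of
    Weisfeiler-Lehman atom colors (canonical labels of the chemical
    substructure around each atom). Pathway features are sums of
    member-compound features. A multi-layer perceptron is trained on the
    block-diagonal per-knowledgebase cross-join of compound and pathway
    feature rows, and evaluated with stratified cross-validation,
    cross-knowledgebase transfer, and a cross-reference consistency analysis
    quantifying how representation standardization affects generalization
    across knowledgebases. A synthetic multi-knowledgebase generator provides
    valence-valid molecules, motif-driven pathway memberships, and
    cross-reference pairs with controlled representation inconsistencies.
License: MIT + file LICENSE
Encoding: UTF-8
SystemRequirements: Open Babel (the obabel executable on the PATH)
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    rlang,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
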