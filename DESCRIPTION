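Package: pathlogit
Title: Multi-Label Metabolic Pathway Inference from Enzyme Annotation Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the set of metabolic pathways encoded in a genome or
    community sample from its profile of enzymatic reaction (EC number)
    annotations. Implements one-vs-rest logistic regression with an
    elastic-net penalty trained by mini-batch subgradient ascent over rich
    engineered feature blocks (reaction abundance, reaction evidence,
    pathway evidence, pathway common, possible pathway), together with a
    Poisson-subsampling synthetic dataset generator with feature-noise
    corruption, iterative multi-label stratified splitting, coverage and
    parsimony (minimal pathway set) baseline predictors, and a multi-label
    evaluation suite (average precision/recall/F1, Hamming loss, RLA/ELA
    robustness scores).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    withr,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
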