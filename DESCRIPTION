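Package: CauloLogic
Title: Multi-Valued Logical Modeling of the Caulobacter crescentus Cell
    Cycle and Cell Fate Network
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A synchronous multi-valued (Thomas-formalism) logical network
    engine together with reconstructed models of the core regulatory
    circuit controlling the cell cycle and asymmetric division of
    Caulobacter crescentus. Provides exhaustive attractor and
    basin-of-attraction enumeration over the full discrete state space,
    in-silico knockout and constitutive-expression scans, the
    swarmer-to-stalked differentiation switch protocol, and Derrida-map
    criticality analysis (perturbation propagation and the slope m at
    h = 0). Includes a seeded random-network ensemble generator and
    brute-force oracles for validation, plus readers/writers for a
    declarative YAML/JSON model format, interaction tables, transition
    graphs (DOT/GraphML) and attractor reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    yaml,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    knitr
biocViews: SystemsBiology, NetworkInference, GraphAndNetwork, CellBiology
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'CauloLogic-package.R'
    'engine.R'
    'models.R'
    'perturbations.R'
    'criticality.R'
    'synthetic.R'
    'io.R'
    'pipeline.R'
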