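Package: BoolIntervene
Title: Minimal Selective Interventions in Boolean Regulatory Networks
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Integer linear programming machinery for finding minimal
    intervention sets that clamp nodes of Boolean regulatory networks so
    that a chosen target node is forced to opposite values in two
    structurally similar networks (repressed in a pathological variant,
    preserved in a healthy one), or to a desired value in a single
    network. Boolean update rules are compiled to AND/OR/NOT gate
    circuits and linearised into mixed-integer programs; an exact
    branch-and-bound solver with no-good cuts enumerates all optimal and
    ranked suboptimal intervention supports, verifies support minimality
    by single-removal re-solves, and validates candidate supports against
    elementary modes of stoichiometric models and against minimal Boolean
    activation routes. Includes parsers and writers for plain-text rule
    files and reaction tables, a reconstruction of the MKMN two-network
    case study, and generators for random structurally similar network
    pairs and toy stoichiometric models.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), boot, optparse
biocViews: Network, GraphAndNetwork, NetworkInference, SystemsBiology
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'BoolIntervene-package.R'
    'boolnet-io.R'
    'stoich.R'
    'fixtures.R'
    'linprog.R'
    'solver.R'
    'em.R'
    'encode.R'
    'enumerate.R'
    'minimality.R'
    'cli.R'
    'simplex.R'
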