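Package: mtmap
Title: Merged Transition Maps for Combinatorial Target Discovery in
    Asynchronous Boolean Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing drug-induced state transitions in
    asynchronous Boolean models of cell signalling. Builds merged
    transition maps (MTMs) linking the attractor landscape of an
    unperturbed network with the landscape obtained after pinning a
    target node, factorises them into desired and undesired path
    ensembles by absorbing Markov chain analysis, and ranks candidate
    synergistic partner targets by their weighted flipping frequency.
    Includes attractor identification by constant-node reduction,
    Monte Carlo basin-of-attraction estimation, multi-stable motif and
    interconnecting-node detection, signal-flow based control-type
    selection, comparator baselines (systematic perturbation screening,
    feedback vertex sets), degree-preserving network randomisation, and
    seeded generators of synthetic conflict networks for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    Matrix,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
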