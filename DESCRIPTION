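Package: evtnet
Title: Expected Visiting Time Analysis of Protein Structure Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models allosteric signal propagation in protein structures as an
    absorbing Markov random walk on an affinity-weighted residue contact
    network. Builds the network from heavy-atom contacts in a PDB structure,
    computes per-residue expected visiting time (EVT) profiles from the
    fundamental matrices of the absorbing chains, derives average signal
    traffic (a betweenness-like centrality), provides a shortest-path
    visiting-time (SVT) baseline, compares profiles between structure pairs,
    and relates traffic to alanine-scanning binding free-energy changes
    through per-complex linear regressions. Includes a synthetic toy-structure
    generator and a Monte-Carlo random-walk oracle for validation.
License: MIT
Encoding: UTF-8
Imports:
    bio3d,
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
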