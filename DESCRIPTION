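Package: atommatch
Title: Symmetry-Aware Atom Mapping in Chemical Reactions by Deep Graph
    Matching
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Learns one-to-one correspondences between reactant and
    product atoms of balanced chemical reactions.  Molecules are parsed
    from SMILES into featurized graphs, a shared-weight graph isomorphism
    network embeds the atoms of both sides, and a softmax-normalized
    affinity matrix yields per-atom matching probabilities.  An adapted
    Weisfeiler-Lehman refinement partitions atoms into classes of
    topologically equivalent atoms so that training and evaluation never
    penalize chemically indistinguishable assignments.  Includes a
    reaction-edit engine that reconstructs balanced products from edit
    lists, a seeded generator of valence-legal synthetic reactions with
    known ground-truth mappings, symmetry-tolerant top-k evaluation, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
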