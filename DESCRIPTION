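Package: tmligen
Title: Inverse Design of Transition-Metal Ligands with a Junction-Tree
    Variational Autoencoder
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for generative design of neutral mono- and bidentate
    transition-metal ligands. Provides a metal-anchored SMILES grammar that
    encodes denticity and formal metal-ligand bond order with placeholder
    atoms and dative-bond tokens, a junction-tree variational autoencoder
    that learns and samples ligands in that grammar, quality metrics for
    generated sets (validity, uniqueness, novelty, internal diversity,
    synthetic accessibility), molecular descriptors including an
    atom-contribution log P and a steric-bulk volume descriptor around the
    metal anchors, and directional single- and dual-objective optimization
    in latent space with Tanimoto similarity gating and post-hoc property
    verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
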