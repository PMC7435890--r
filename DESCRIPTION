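Package: vaesim
Title: Molecular Similarity from a SMILES Variational Autoencoder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Learns a continuous latent representation of molecules by training
    a variational autoencoder on character-level one-hot encodings of SMILES
    strings, and turns distances in that latent space into a molecular
    similarity metric (E-Sim on the full latent vectors, EU-Sim on their
    two-dimensional UMAP projection). Includes the classical nine-fingerprint
    Tanimoto baseline (MACCS, Morgan, FeatMorgan, Atom Pair, Torsion, RDKit,
    Layered, Pattern, Avalon) for side-by-side comparison, a seeded generator
    of small synthetic molecules for desk-scale training, bundled reference
    drug structures, and a command-line interface covering the full pipeline
    from SMILES ingestion through training to nearest-neighbour search.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
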