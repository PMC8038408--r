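Package: fragnet
Title: Contrastive Transformer Autoencoder Latent Spaces for Small Molecules
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds disentangled molecular latent spaces by training a
    transformer sequence autoencoder on SMILES strings with a joint
    NT-Xent contrastive objective over enumerated-SMILES positive pairs
    and a masked-decoder reconstruction objective. Provides SMILES
    canonicalization, Bjerrum-style enumeration augmentation, atomwise
    tokenization and vocabularies, the full encoder/projection/
    unprojection/decoder architecture with native backpropagation and
    Adam training, and latent-space diagnostics: cosine/Euclidean/
    Tanimoto neighbor retrieval, temperature cross-comparison tables,
    dimension-population sparsity traces, per-dimension histograms with
    representative molecules, and seeded t-SNE/UMAP 2-D maps. Includes
    a synthetic scaffold-family SMILES generator so the whole pipeline
    is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    digest,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    Rtsne,
    uwot,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Cheminformatics, MachineLearning, DimensionReduction
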