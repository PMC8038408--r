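---
title: "Contrastive transformer embeddings of chemical space with fragnet"
author: "Package Author"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contrastive transformer embeddings of chemical space with fragnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragnet)
```

# Overview

`fragnet` implements a contrastive-learning transformer autoencoder over
SMILES strings. A molecule is a point in a learned latent space in which
cosine similarity reflects structural similarity; the same latent vector
can be decoded back to a SMILES string. The package covers the full
pipeline: SMILES parsing, canonicalization and enumeration; atomwise
tokenization and vocabulary construction; the transformer
encoder/projection/unprojection/decoder stack with hand-derived
backpropagation; the NT-Xent and reconstruction objectives with Adam
training; latent-space diagnostics (neighbor retrieval, dimension
sparsity, 2-D maps); synthetic fixture corpora; and a command-line
interface.

This vignette documents the model, the numerical choices, the synthetic
data generator and its realism limits, the desk-scale study conditions,
and known limitations.

# The model

## Input representation

SMILES strings are tokenized atomwise: bracket atoms (`[nH]`), the
two-letter halogens `Cl`/`Br` and `%nn` ring closures are single tokens;
every other character is its own token. Concatenating the tokens always
reproduces the input. The vocabulary fixes four special tokens at indices
0--3 (`<pad>`, `<s>`, `</s>`, `<unk>`); chemical tokens follow in
lexicographic byte order. All indices in the public API are 0-based;
`encodeSequence()` frames a string as `<s> tokens </s> <pad>...` of fixed
length `maxLen` and refuses strings that do not fit rather than
truncating.

Because augmentation can produce tokens absent from the canonical
corpus (branch parentheses, ring digits), `buildVocabulary()` runs
seeded enumeration passes over the corpus during token collection.

## Architecture

The encoder is a standard transformer: token embedding scaled by
$\sqrt{d_{model}}$ plus sinusoidal positional encoding, then `nBlocks`
blocks of multi-head self-attention and position-wise feed-forward
layers, each wrapped in residual connections and layer normalization.
Padding positions are masked out of attention, so the representation of
the real tokens is invariant to the amount of padding (tested).

The *projection head* flattens the padding-zeroed encoder output
($L \times d_{model}$) and applies four fully connected layers, each
followed by a ReLU, tapering to a latent vector $z$ of length
$d_{model}$. Because the last layer is also ReLU-terminated, latent
entries are non-negative and can be exactly zero — this is what makes
the dimension-population sparsity analysis meaningful (a dimension is
"off", not just small). The *unprojection head* mirrors it (three ReLU
layers, final layer linear) and reshapes its output to an
$L \times d_{model}$ decoder memory.

The decoder is a masked transformer decoder: causal self-attention over
the shifted-right target sequence, cross-attention reading keys and
values from the memory, and a final linear + softmax over the
vocabulary. Position $t$ of the output predicts token $t+1$ and can
only see targets at positions $\le t$ (tested property).

## Objectives

Training minimizes a weighted sum of two losses over a batch of $N$
molecules, each contributing two *enumerated* views (random-restart
rewritings of the same molecular graph):

* **NT-Xent** over the $2N$ latent vectors with cosine similarity and
  temperature $\tau$: for anchor $i$ with positive $j$,
  $\ell_i = -\log \frac{\exp(\mathrm{sim}(z_i,z_j)/\tau)}
  {\sum_{k \ne i}\exp(\mathrm{sim}(z_i,z_k)/\tau)}$, averaged over all
  anchors. (The common printed form of this loss omits the minus sign,
  which would make it non-positive; the implementation uses the
  conventional negative log.)
* **Reconstruction cross-entropy**: mean negative log-probability of the
  true next token over non-padding positions, decoding each view from
  its own latent vector.

Canonical SMILES never enter training; they are used only afterwards to
embed a corpus (`embedCorpus()`), so the latent position of a molecule is
well-defined.

# Numerical choices

No deep-learning framework is available in this R stack, so forward and
backward passes are implemented natively with matrix operations. Choices
worth recording:

* **Gradient correctness** is guarded by finite-difference tests: the
  analytic gradient of the full composite loss matches central
  differences (sampled weights across all parameter groups) to a
  relative error of order $10^{-5}$.
* **Softmax stabilization**: attention and NT-Xent exponentials are
  max-shifted before exponentiation; masked attention logits are set to
  $-10^{30}$ and their probability mass is exactly zeroed in the
  backward pass.
* **Zero latent vectors**: the ReLU projection head can output an
  all-zero $z$; cosine similarity involving a zero vector is defined as
  0 with a warning and its gradient contribution is zero.
* **Optimizer**: Adam ($\beta_1 = 0.9$, $\beta_2 = 0.999$,
  $\epsilon = 10^{-8}$) on a flattened parameter vector with bias
  correction.
* **Determinism**: a master seed fans out via `sample.int` into separate
  initialisation and shuffle/augmentation/dropout streams; training twice
  with the same seed gives bit-identical weights. Seeded helpers save
  and restore the caller's RNG state. t-SNE uses exact mode
  (`theta = 0`) and UMAP runs single-threaded so maps are reproducible.
* **Checkpoints** are a single JSON file with 17-significant-digit
  weights and a SHA-256 vocabulary hash verified on load.

# Chemistry backends

Canonicalization and fingerprints delegate to Open Babel (via
`ChemmineOB`): SMILES → canonical SMILES, and FP2 1024-bit path-based
fingerprints for Tanimoto similarity (the same fingerprint family as
path-based RDKit fingerprints). Open Babel is lenient about malformed
input, so the package validates SMILES first with its own strict graph
parser; the same parser drives enumeration, which rewrites the molecular
graph from a uniformly random root atom with randomly permuted neighbor
order. Stereochemistry descriptors are refused by enumeration because
atom reordering would silently change their meaning.

# Synthetic fixtures and generator realism

Real training corpora in this problem family are $10^5$--$10^6$
molecules; at desk scale the package ships generated stand-ins:

* `defaultFixture("tiny")` — five short molecules for memorization
  probes.
* `defaultFixture("small")` — three scaffold families (benzene,
  cyclohexane, pyridine; 8 members each) produced by
  `generateFamilies()`, which substitutes sampled fragment pairs into
  asymmetric scaffold templates, canonicalizes and de-duplicates. The
  frozen seed makes the corpus byte-identical across runs.
* `recycledCorpus(n)` — recycles fixture SMILES under fresh ids to any
  size, for split/batch arithmetic that only counts rows.

Realism limits: the generated molecules are small (≤ ~15 heavy atoms),
drug-like only in a loose decorative sense, uncharged, stereochemistry
free, and within a family differ only by substituents — which is exactly
the controlled structure the clustering studies need (within-family
Tanimoto exceeds between-family Tanimoto, tested), but far narrower than
real chemical space. Conclusions at this scale demonstrate that the
machinery works, not that the published large-scale chemistry holds.

# Desk-scale study conditions

The published regime (450-token sequences, $d_{model}$ 64--256, weeks of
GPU time, ~160k molecules) is out of reach in a CPU test environment, so
the package defines two frozen probes whose problem sizes are its own
choice:

* **Memorization probe**: tiny fixture, `maxLen` 24, $d_{model}$ 32, 4
  blocks, 4 heads, dropout 0, $\tau$ 0.05, batch 5, learning rate
  $10^{-3}$, seed 7, 400 steps, `augment = FALSE` (each record is its
  own positive pair). Under full augmentation the contrastive term makes
  the latent deliberately view-invariant, so greedy decoding returns
  *some* valid rewriting of the molecule rather than the exact input
  string; disabling augmentation isolates the autoencoder path, which
  then reproduces all five training strings exactly.
* **Clustering probe**: small fixture, `maxLen` 32, $d_{model}$ 32, 4
  blocks, 4 heads, dropout 0.2, $\tau$ 0.05, batch 8, learning rate
  $10^{-3}$, seed 11, 450 steps, full augmentation. After training,
  mean within-family cosine similarity of canonical-SMILES latents
  clearly exceeds the between-family mean (≈ 0.70 vs ≈ 0.35 observed),
  and held-out positive pairs are far more similar than mismatched
  pairs (≈ 0.99 vs ≈ 0.38 observed).

Both stay well under the acceptance step caps and run in minutes on one
CPU.

# A short worked example

```{r example, eval = FALSE}
recs <- defaultFixture("small")
vocab <- buildVocabulary(recs, seed = 1L)
cfg <- fragnetConfig(vocabSize = vocabSize(vocab), maxLen = 32L,
                     dModel = 32L, nBlocks = 4L, nHeads = 4L,
                     dropout = 0.2, temperature = 0.05, batchSize = 8L,
                     learningRate = 1e-3, epochs = 200L, seed = 11L)
fit <- trainFragNet(recs, cfg, vocab, maxSteps = 450L)
lat <- embedCorpus(recs, fit$model)
familySimilarityGap(lat, recs$family)
neighborQuery(list(id = recs$id[1], smiles = recs$smiles[1]),
              lat, recs, metric = "cosine", k = 5L)
dimensionPopulation(lat)
map2d(lat, method = "tsne", seed = 3L, labels = recs$family)
```

(Evaluation is disabled in this vignette because the training step takes
a few minutes; the README shows the same pipeline with captured output.)

# Limitations

* Native-R training is orders of magnitude slower than a GPU framework;
  the package is a faithful, verifiable desk-scale implementation, not a
  production trainer.
* Enumeration (and therefore training) excludes stereochemistry; charged
  and multi-fragment (dot-separated) SMILES are rejected by the strict
  parser.
* Greedy decoding of an arbitrary latent point may produce invalid
  SMILES; callers should validate with `canonicalizeSmiles()`.
* The latent dimensionality equals `dModel`; no bottleneck smaller than
  the embedding width is currently supported.
* Dropout regularisation uses a shared RNG stream with augmentation and
  shuffling; per-component streams would allow finer ablation.
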