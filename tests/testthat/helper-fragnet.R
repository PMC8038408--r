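# Shared helpers for the test suite.

# Independent brute-force NT-Xent reference: explicit double loop over
# anchors and negatives, no stabilisation, no vectorisation. Kept
# deliberately different in structure from ntXent() so the two can serve
# as mutual oracles.
ntXentOracle <- function(z, tau) {
  n <- nrow(z)
  sim <- function(a, b) {
    na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
    if (na == 0 || nb == 0) return(0)
    sum(a * b) / (na * nb)
  }
  total <- 0
  for (i in seq_len(n)) {
    j <- if (i %% 2 == 1) i + 1 else i - 1
    num <- exp(sim(z[i, ], z[j, ]) / tau)
    den <- 0
    for (k in seq_len(n)) if (k != i) den <- den + exp(sim(z[i, ], z[k, ]) / tau)
    total <- total - log(num / den)
  }
  total / n
}

# A small untrained model for structural tests (shapes, masking,
# causality, checkpoints); chemistry-light and fast to build.
testModel <- function(maxLen = 16L, dModel = 8L, nBlocks = 1L,
                      nHeads = 2L, seed = 5L,
                      corpus = c("CCO", "c1ccccc1", "CC(=O)O")) {
  vocab <- buildVocabulary(corpus, enumPasses = 2L, seed = 1L)
  cfg <- fragnetConfig(vocabSize = vocabSize(vocab), maxLen = maxLen,
                       dModel = dModel, nBlocks = nBlocks, nHeads = nHeads,
                       dropout = 0, temperature = 0.1, batchSize = 2L,
                       learningRate = 1e-3, seed = seed)
  fragnetInit(cfg, vocab)
}

# Random LatentMatrix for analysis tests that need no chemistry.
randomLatents <- function(n, d, seed = 1L, nonneg = TRUE) {
  set.seed(seed)
  V <- matrix(rnorm(n * d), n, d)
  if (nonneg) V <- abs(V)
  latentMatrix(sprintf("m%03d", seq_len(n)), V, 0.05)
}
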