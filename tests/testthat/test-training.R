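test_that("splitDataset honours the 3:2 ratio on five records", {
  recs <- defaultFixture("tiny")
  sp <- splitDataset(recs, 3 / 5, seed = 1L)
  expect_equal(nrow(sp$train), 3L)
  expect_equal(nrow(sp$validation), 2L)
})

test_that("splitDataset is a disjoint exhaustive partition (property)", {
  recs <- recycledCorpus(137L)
  for (f in c(0.1, 0.5, 5 / 6)) {
    sp <- splitDataset(recs, f, seed = 9L)
    expect_equal(nrow(sp$train), floor(f * 137))
    expect_setequal(c(sp$train$id, sp$validation$id), recs$id)
    expect_length(intersect(sp$train$id, sp$validation$id), 0L)
  }
  expect_error(splitDataset(recs, 0), "trainFraction")
  expect_error(splitDataset(recs, 1), "trainFraction")
})

test_that("splitDataset is seeded and leaves the caller RNG untouched", {
  recs <- recycledCorpus(50L)
  set.seed(123); before <- .Random.seed
  s1 <- splitDataset(recs, 0.6, seed = 4L)
  expect_identical(.Random.seed, before)
  s2 <- splitDataset(recs, 0.6, seed = 4L)
  expect_identical(s1$train$id, s2$train$id)
})

test_that("makeBatches drops the trailing incomplete batch", {
  recs <- recycledCorpus(10L)
  b <- makeBatches(recs, 3L, seed = 2L)
  expect_length(b, 3L)
  expect_true(all(vapply(b, nrow, 0L) == 3L))
  bAll <- makeBatches(recs, 3L, dropLast = FALSE, seed = 2L)
  expect_length(bAll, 4L)
  expect_equal(nrow(bAll[[4]]), 1L)
  expect_setequal(unlist(lapply(bAll, `[[`, "id")), recs$id)
  expect_error(makeBatches(recs, 1L), "batchSize")
})

test_that("flat/unflat parameter mapping is a lossless inverse", {
  m <- testModel()
  v <- fragnet:::.flatW(m@weights)
  back <- fragnet:::.unflatW(v, m@weights)
  expect_equal(back, m@weights, tolerance = 0)
  expect_equal(fragnet:::.flatW(back), v)
})

test_that("adam takes a finite descent-scaled step", {
  st <- fragnet:::.adamInit(3L)
  w <- c(1, -2, 0.5); g <- c(0.1, -0.3, 0)
  up <- fragnet:::.adamStep(w, g, st, lr = 0.01)
  # first step moves each coordinate by ~lr against the gradient sign
  expect_equal(up$w[1], w[1] - 0.01, tolerance = 1e-5)
  expect_equal(up$w[2], w[2] + 0.01, tolerance = 1e-5)
  expect_equal(up$w[3], w[3])
  expect_equal(up$state$t, 1L)
})

test_that("training consumes augmented views, never canonical inputs only", {
  recs <- defaultFixture("small")[c(1, 9, 17, 20), ]
  vocab <- buildVocabulary(recs, enumPasses = 5L, seed = 1L)
  cfg <- fragnetConfig(vocabSize = vocabSize(vocab), maxLen = 32L,
                       dModel = 8L, nBlocks = 1L, nHeads = 2L, dropout = 0,
                       temperature = 0.1, batchSize = 4L,
                       learningRate = 1e-3, epochs = 3L, seed = 2L)
  res <- trainFragNet(recs, cfg, vocab, maxSteps = 3L, trace = TRUE)
  expect_length(res$inputs, 3L * 2L * 4L)
  # every consumed string is a view of some corpus molecule
  expect_true(all(canonicalizeSmiles(res$inputs) %in% recs$smiles))
  # and augmentation actually rewrites: not all strings are canonical
  expect_gt(sum(!(res$inputs %in% recs$smiles)), 0L)
})

test_that("trainFragNet is deterministic under its master seed", {
  recs <- defaultFixture("tiny")
  vocab <- buildVocabulary(recs, enumPasses = 3L, seed = 1L)
  cfg <- fragnetConfig(vocabSize = vocabSize(vocab), maxLen = 24L,
                       dModel = 8L, nBlocks = 1L, nHeads = 2L,
                       dropout = 0.1, temperature = 0.1, batchSize = 5L,
                       learningRate = 1e-3, epochs = 2L, seed = 77L)
  r1 <- trainFragNet(recs, cfg, vocab)
  r2 <- trainFragNet(recs, cfg, vocab)
  expect_identical(r1$metrics, r2$metrics)
  expect_equal(r1$model@weights, r2$model@weights, tolerance = 0)
})

test_that("trainFragNet records per-step metrics and respects maxSteps", {
  recs <- defaultFixture("tiny")
  vocab <- buildVocabulary(recs, enumPasses = 3L, seed = 1L)
  cfg <- fragnetConfig(vocabSize = vocabSize(vocab), maxLen = 24L,
                       dModel = 8L, nBlocks = 1L, nHeads = 2L, dropout = 0,
                       temperature = 0.1, batchSize = 2L,
                       learningRate = 1e-3, epochs = 10L, seed = 5L)
  res <- trainFragNet(recs, cfg, vocab, maxSteps = 4L)
  expect_equal(nrow(res$metrics), 4L)
  expect_named(res$metrics,
               c("epoch", "batch", "contrastive", "reconstruction", "total"))
  expect_true(all(is.finite(res$metrics$total)))
  expect_equal(res$metrics$total,
               res$metrics$contrastive + res$metrics$reconstruction)
})

test_that("the loss decreases on a short overfitting run", {
  recs <- defaultFixture("tiny")
  vocab <- buildVocabulary(recs, enumPasses = 3L, seed = 1L)
  cfg <- fragnetConfig(vocabSize = vocabSize(vocab), maxLen = 24L,
                       dModel = 16L, nBlocks = 1L, nHeads = 2L, dropout = 0,
                       temperature = 0.1, batchSize = 5L,
                       learningRate = 1e-3, epochs = 30L, seed = 8L)
  res <- trainFragNet(recs, cfg, vocab, maxSteps = 30L, augment = FALSE)
  first5 <- mean(res$metrics$total[1:5])
  last5 <- mean(res$metrics$total[26:30])
  expect_lt(last5, first5)
})

test_that("config/vocabulary size mismatch is rejected", {
  recs <- defaultFixture("tiny")
  vocab <- buildVocabulary(recs, enumPasses = 3L, seed = 1L)
  cfg <- fragnetConfig(vocabSize = vocabSize(vocab) + 1L, maxLen = 24L,
                       dModel = 8L, nBlocks = 1L, nHeads = 2L,
                       batchSize = 2L)
  expect_error(trainFragNet(recs, cfg, vocab), "vocabSize")
})
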