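test_that("embedCorpus is deterministic with non-negative latents", {
  m <- testModel(corpus = defaultFixture("tiny")$smiles)
  recs <- defaultFixture("tiny")
  l1 <- embedCorpus(recs, m)
  l2 <- embedCorpus(recs, m)
  expect_identical(latentVectors(l1), latentVectors(l2))
  expect_identical(latentIds(l1), recs$id)
  expect_true(all(latentVectors(l1) >= 0))
  expect_equal(l1@sourceTemperature, m@config@temperature)
})

test_that("neighborQuery agrees with brute-force ranking", {
  lat <- randomLatents(30L, 6L, seed = 4L)
  corpus <- data.frame(id = latentIds(lat),
                       smiles = rep(defaultFixture("tiny")$smiles, 6),
                       stringsAsFactors = FALSE)
  q <- list(id = latentIds(lat)[7], smiles = corpus$smiles[7])
  res <- neighborQuery(q, lat, corpus, metric = "cosine", k = 30L)
  V <- latentVectors(lat)
  bf <- apply(V, 1L, function(r) cosineSim(r, V[7, ]))
  expect_identical(res$neighbor_id,
                   latentIds(lat)[order(-bf, latentIds(lat),
                                        method = "radix")])
  expect_equal(res$cosine, unname(sort(bf, decreasing = TRUE)),
               tolerance = 1e-12)
  # the query ranks itself first under cosine
  expect_identical(res$neighbor_id[1], q$id)
  # euclidean ranking ascends
  resE <- neighborQuery(q, lat, corpus, metric = "euclidean", k = 5L)
  expect_false(is.unsorted(resE$euclidean))
  expect_error(neighborQuery(q, lat, corpus, k = 31L), "exceeds")
})

test_that("unit-sphere identity d^2 = 2 - 2 cos links the two metrics", {
  lat <- randomLatents(20L, 8L, seed = 6L)
  V <- latentVectors(lat)
  U <- V / sqrt(rowSums(V^2))
  latU <- latentMatrix(latentIds(lat), U)
  corpus <- data.frame(id = latentIds(lat), smiles = "CCO",
                       stringsAsFactors = FALSE)
  q <- list(id = latentIds(lat)[1], smiles = "CCO")
  res <- neighborQuery(q, latU, corpus, metric = "cosine", k = 20L)
  expect_equal(res$euclidean^2, 2 - 2 * res$cosine, tolerance = 1e-9)
})

test_that("tanimoto similarity behaves like a set overlap", {
  expect_equal(tanimotoSimilarity("c1ccccc1O", "c1ccccc1O"), 1)
  s <- tanimotoSimilarity("c1ccccc1O", "CCCCCCCC")
  expect_gte(s, 0); expect_lt(s, 0.3)
  expect_equal(s, tanimotoSimilarity("CCCCCCCC", "c1ccccc1O"))
  # matches an explicit set computation on the exposed bit sets
  bits <- fingerprintBits(c("c1ccccc1O", "c1ccccc1N"))
  expect_equal(tanimotoSimilarity("c1ccccc1O", "c1ccccc1N"),
               length(intersect(bits[[1]], bits[[2]])) /
                 length(union(bits[[1]], bits[[2]])))
})

test_that("similarityScatter pairs metrics and excludes the query", {
  lat <- randomLatents(10L, 4L, seed = 2L)
  corpus <- data.frame(id = latentIds(lat), smiles = "CCO",
                       stringsAsFactors = FALSE)
  q <- list(id = latentIds(lat)[3], smiles = "CCO")
  sc <- similarityScatter(q, lat, metricX = "cosine", metricY = "euclidean")
  expect_equal(nrow(sc), 9L)
  expect_false(q$id %in% sc$id)
  V <- latentVectors(lat)
  i <- match(sc$id[1], latentIds(lat))
  expect_equal(sc$x[1], cosineSim(V[i, ], V[3, ]), tolerance = 1e-12)
  expect_equal(sc$y[1], sqrt(sum((V[i, ] - V[3, ])^2)), tolerance = 1e-12)
  expect_match(attr(sc, "xlab"), "cosine")
})

test_that("dimension-population traces match hand-computed values", {
  id3 <- dimensionPopulation(diag(3))
  expect_equal(id3$alwaysNonzero, 0L)
  expect_equal(id3$meanNonzero, 1)
  expect_equal(id3$maxNonzero, 1)
  zero <- dimensionPopulation(matrix(0, 4, 5))
  expect_equal(zero$alwaysNonzero, 0L)
  expect_equal(zero$meanNonzero, 0)
  expect_equal(zero$maxNonzero, 0)
  mixed <- dimensionPopulation(rbind(c(1, 1), c(1, 0)))
  expect_equal(mixed$alwaysNonzero, 1L)
  expect_equal(mixed$meanNonzero, 1.5)
  expect_equal(mixed$maxNonzero, 2)
  expect_equal(mixed$dimensionality, 2L)
})

test_that("dimension-population invariant always <= mean <= max <= D", {
  set.seed(31)
  for (i in 1:25) {
    V <- matrix(rnorm(60), 10, 6) * (matrix(runif(60), 10, 6) > 0.4)
    dp <- dimensionPopulation(V)
    expect_lte(dp$alwaysNonzero, dp$meanNonzero)
    expect_lte(dp$meanNonzero, dp$maxNonzero)
    expect_lte(dp$maxNonzero, dp$dimensionality)
  }
})

test_that("dimension histogram conserves counts and picks central reps", {
  lat <- randomLatents(40L, 5L, seed = 8L)
  h <- dimensionHistogram(lat, dim = 2L, nBins = 10L, nReps = 2L)
  expect_equal(sum(h$counts), 40L)
  expect_length(h$mids, 10L)
  b <- which(h$counts > 0)[1]
  ids <- h$representatives[[b]]
  x <- latentVectors(lat)[, 2]
  inBin <- latentIds(lat)[x >= h$breaks[b] & x <= h$breaks[b + 1]]
  expect_true(all(ids %in% inBin))
  # constant dimension: single widened bin, no crash
  latC <- latentMatrix(letters[1:5], matrix(1, 5, 2))
  hC <- dimensionHistogram(latC, 1L, nBins = 4L)
  expect_equal(sum(hC$counts), 5L)
  expect_error(dimensionHistogram(lat, 99L), "dim")
})

test_that("familySimilarityGap separates constructed clusters", {
  set.seed(5)
  A <- matrix(rep(c(10, 0, 0, 0), each = 6), 6, 4) + rnorm(24, sd = 0.1)
  B <- matrix(rep(c(0, 10, 0, 0), each = 6), 6, 4) + rnorm(24, sd = 0.1)
  lat <- latentMatrix(sprintf("x%02d", 1:12), rbind(A, B))
  gap <- familySimilarityGap(lat, rep(c("a", "b"), each = 6))
  expect_gt(gap$within, 0.99)
  expect_lt(gap$between, 0.1)
  expect_equal(gap$gap, gap$within - gap$between)
})

test_that("2-D maps are seeded-deterministic and keep clusters apart", {
  set.seed(9)
  A <- matrix(rnorm(10 * 6, mean = 0), 10, 6)
  B <- matrix(rnorm(10 * 6, mean = 8), 10, 6)
  lat <- latentMatrix(sprintf("p%02d", 1:20), rbind(A, B))
  co1 <- map2d(lat, "tsne", seed = 3L)
  co2 <- map2d(lat, "tsne", seed = 3L)
  expect_identical(co1, co2)
  cA <- colMeans(co1[1:10, , drop = FALSE])
  cB <- colMeans(co1[11:20, , drop = FALSE])
  # every point sits nearer its own cluster centroid
  dA <- sqrt(colSums((t(co1) - cA)^2)); dB <- sqrt(colSums((t(co1) - cB)^2))
  expect_true(all(dA[1:10] < dB[1:10]))
  expect_true(all(dB[11:20] < dA[11:20]))
})

test_that("umap map runs seeded with csv/png outputs", {
  lat <- randomLatents(15L, 5L, seed = 3L)
  csv <- tempfile(fileext = ".csv"); png <- tempfile(fileext = ".png")
  co <- map2d(lat, "umap", seed = 7L, labels = rep(c("a", "b", "c"), 5),
              outCsv = csv, outPng = png)
  expect_equal(dim(co), c(15L, 2L))
  expect_true(file.exists(csv) && file.exists(png))
  expect_identical(co, map2d(lat, "umap", seed = 7L))
})
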