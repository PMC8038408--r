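test_that("canonicalization is idempotent and merges equivalent strings", {
  v <- canonicalizeSmiles(c("OCC", "CCO", "C(C)O"))
  expect_equal(v[1], v[2])
  expect_equal(v[1], v[3])
  expect_equal(canonicalizeSmiles(v), v)
})

test_that("invalid SMILES are rejected before reaching the toolkit", {
  expect_error(canonicalizeSmiles("C("), "unclosed|unbalanced|branch")
  expect_error(canonicalizeSmiles("C1CC"), "ring")
  expect_error(canonicalizeSmiles("CC)"), "unbalanced|unopened|branch")
  expect_error(canonicalizeSmiles(""), "empty")
  expect_error(canonicalizeSmiles("C[N"), "bracket")
})

test_that("tokenizer keeps multi-character tokens whole", {
  expect_identical(tokenizeSmiles("C(Cl)Br"), c("C", "(", "Cl", ")", "Br"))
  expect_identical(tokenizeSmiles("[nH]1cccc1"),
                   c("[nH]", "1", "c", "c", "c", "c", "1"))
  expect_identical(tokenizeSmiles("C%12CC%12"), c("C", "%12", "C", "C", "%12"))
  expect_identical(tokenizeSmiles(""), character(0))
})

test_that("tokenization concatenates back to the input (property)", {
  for (s in c(defaultFixture("tiny")$smiles, "O=C(O)c1ccccc1OC(C)=O",
              "C[C@H](N)C(=O)O", "[Na+].[Cl-]")) {
    expect_identical(paste(tokenizeSmiles(s), collapse = ""), s)
  }
})

test_that("vocabulary places specials first with fixed ids", {
  vocab <- buildVocabulary("CCO", enumPasses = 0L)
  expect_equal(vocabSize(vocab), 6L)   # 4 specials + C + O
  expect_identical(vocab@tokens[1:4], c("<pad>", "<s>", "</s>", "<unk>"))
  expect_identical(tokenIndex(vocab, c("<pad>", "<s>", "</s>", "<unk>")),
                   0:3)
  expect_identical(vocab@tokens[5:6], c("C", "O"))
})

test_that("vocabulary construction is deterministic and covers enumerations", {
  recs <- defaultFixture("small")
  v1 <- buildVocabulary(recs, enumPasses = 5L, seed = 3L)
  v2 <- buildVocabulary(recs, enumPasses = 5L, seed = 3L)
  expect_identical(v1@tokens, v2@tokens)
  enum <- enumerateSmiles(recs$smiles[1], n = 5L, seed = 9L)
  toks <- unique(unlist(lapply(enum, tokenizeSmiles)))
  expect_true(all(toks %in% v1@tokens))
})

test_that("encodeSequence frames, pads and refuses over-length input", {
  vocab <- buildVocabulary("CCO", enumPasses = 0L)
  es <- encodeSequence("CCO", vocab, maxLen = 8L)
  expect_identical(es$tokenIds,
                   c(1L, 4L, 4L, 5L, 2L, 0L, 0L, 0L))
  expect_equal(es$trueLength, 5L)
  expect_identical(es$padMask, c(rep(FALSE, 5), rep(TRUE, 3)))
  expect_error(encodeSequence("CCCCCCCCC", vocab, maxLen = 8L), "maxLen")
})

test_that("out-of-vocabulary handling maps to unk or errors", {
  vocab <- buildVocabulary("CCO", enumPasses = 0L)
  es <- encodeSequence("CNO", vocab, maxLen = 8L, oov = "unk")
  expect_equal(es$tokenIds[3], 3L)                # N -> <unk>
  expect_error(encodeSequence("CNO", vocab, maxLen = 8L, oov = "error"),
               "out-of-vocabulary")
})

test_that("decodeSequence inverts encodeSequence for in-vocab strings", {
  recs <- defaultFixture("small")
  vocab <- buildVocabulary(recs, enumPasses = 2L, seed = 1L)
  for (s in recs$smiles[c(1, 9, 17)]) {
    es <- encodeSequence(s, vocab, maxLen = 40L)
    expect_identical(decodeSequence(es$tokenIds, vocab), s)
  }
})

test_that("enumeration yields valid same-molecule SMILES", {
  parent <- canonicalizeSmiles("CC(=O)Oc1ccccc1C(=O)O")
  en <- enumerateSmiles(parent, n = 12L, seed = 4L)
  expect_length(en, 12L)
  expect_true(all(canonicalizeSmiles(en) == parent))
  expect_gt(length(unique(en)), 5L)     # genuinely different writings
})

test_that("enumeration is seeded and refuses stereochemistry", {
  expect_identical(enumerateSmiles("c1ccccc1O", n = 5L, seed = 2L),
                   enumerateSmiles("c1ccccc1O", n = 5L, seed = 2L))
  expect_error(enumerateSmiles("C/C=C/C"), "stereo")
  expect_error(enumerateSmiles("C[C@H](N)O"), "stereo")
})

test_that("positive pairs are two views of the parent molecule", {
  rec <- moleculeRecords("CC(=O)Oc1ccccc1C(=O)O", id = "asp")
  set.seed(11)
  pair <- samplePositivePair(rec[1, ])
  expect_equal(pair$parent_id, "asp")
  expect_equal(canonicalizeSmiles(pair$x_i), rec$smiles)
  expect_equal(canonicalizeSmiles(pair$x_j), rec$smiles)
})

test_that("molecule records validate labels and ids", {
  expect_error(moleculeRecords("CCO", label = "polymer"), "label")
  expect_error(moleculeRecords(c("C", "C"), id = c("a", "a")), "duplicate")
  df <- moleculeRecords(c("OCC", "c1ccccc1"), label = c("drug", "other"))
  expect_identical(df$smiles[1], canonicalizeSmiles("CCO"))
})

test_that("corpus files round-trip through csv and smi", {
  recs <- defaultFixture("tiny")
  csv <- tempfile(fileext = ".csv"); smi <- tempfile(fileext = ".smi")
  writeMolecules(recs, csv)
  back <- readMolecules(csv)
  expect_identical(back$smiles, recs$smiles)
  expect_identical(back$id, recs$id)
  writeLines(paste(recs$smiles, recs$id), smi)
  back2 <- readMolecules(smi)
  expect_identical(back2$smiles, recs$smiles)
  expect_identical(back2$id, recs$id)
})

test_that("vocabulary files are byte-stable and round-trip", {
  vocab <- buildVocabulary(defaultFixture("tiny"), enumPasses = 2L, seed = 1L)
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  writeVocabulary(vocab, f1); writeVocabulary(vocab, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readVocabulary(f1)@tokens, vocab@tokens)
})
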