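# The architecture: token embedding + positional encoding -> transformer
# encoder (nBlocks x {multi-head self-attention, add&norm, position-wise
# feed-forward, add&norm}) -> representation h (maxLen x dModel);
# projection head (4 affine+ReLU layers on the flattened, pad-zeroed h)
# -> latent z (dModel, non-negative); unprojection head (mirror, last
# layer linear) -> decoder memory; masked transformer decoder with cross
# attention on that memory -> final linear + softmax over the vocabulary.

.glorot <- function(fin, fout) {
  s <- sqrt(6 / (fin + fout))
  matrix(stats::runif(fin * fout, -s, s), fin, fout)
}

.initAttn <- function(D) list(
  Wq = .glorot(D, D), bq = numeric(D),
  Wk = .glorot(D, D), bk = numeric(D),
  Wv = .glorot(D, D), bv = numeric(D),
  Wo = .glorot(D, D), bo = numeric(D))

.initLn <- function(D) list(g = rep(1, D), b = numeric(D))

.initFfn <- function(D, F) list(
  W1 = .glorot(D, F), b1 = numeric(F),
  W2 = .glorot(F, D), b2 = numeric(D))

.initWeights <- function(cfg) {
  D <- cfg@dModel; L <- cfg@maxLen; V <- cfg@vocabSize; F <- cfg@ffDim
  pd <- c(L * D, cfg@projHidden, D)          # projection layer dims
  ud <- c(D, rev(cfg@projHidden), L * D)     # unprojection mirrors it
  list(
    emb = matrix(stats::rnorm(V * D, sd = 0.05), V, D),
    enc = lapply(seq_len(cfg@nBlocks), function(i) list(
      attn = .initAttn(D), ln1 = .initLn(D),
      ffn = .initFfn(D, F), ln2 = .initLn(D))),
    proj = lapply(seq_len(4L), function(i) list(
      W = .glorot(pd[i], pd[i + 1L]), b = numeric(pd[i + 1L]))),
    unproj = lapply(seq_len(4L), function(i) list(
      W = .glorot(ud[i], ud[i + 1L]), b = numeric(ud[i + 1L]))),
    dec = lapply(seq_len(cfg@nBlocks), function(i) list(
      self = .initAttn(D), ln1 = .initLn(D),
      cross = .initAttn(D), ln2 = .initLn(D),
      ffn = .initFfn(D, F), ln3 = .initLn(D))),
    out = list(W = .glorot(D, V), b = numeric(V)))
}

#' Initialise an untrained model
#'
#' Draws Glorot-uniform weights (layer norm gains 1, biases 0) from the
#' configuration's seed, so initialisation is reproducible.
#'
#' @param config a [FragNetConfig-class]
#' @param vocabulary a [TokenVocabulary-class]; its size must match
#'   \code{config@vocabSize}
#' @return a [FragNetModel-class]
#' @export
fragnetInit <- function(config, vocabulary) {
  stopifnot(config@vocabSize == vocabSize(vocabulary))
  w <- .withSeed(config@seed, .initWeights(config))
  new("FragNetModel", config = config, vocabulary = vocabulary,
      weights = w, vocabHash = .vocabHash(vocabulary))
}

## ---- encoder ------------------------------------------------------------

.encFwd <- function(W, cfg, ids0, padMask, training = FALSE) {
  L <- length(ids0); D <- cfg@dModel
  E <- W$emb[ids0 + 1L, , drop = FALSE] * sqrt(D) +
    .pe(cfg@maxLen, D)[seq_len(L), , drop = FALSE]
  ed <- .dropFwd(E, cfg@dropout, training)
  x <- ed$out
  keyOK <- !padMask
  mask <- matrix(keyOK, L, L, byrow = TRUE)
  blocks <- vector("list", cfg@nBlocks)
  for (i in seq_len(cfg@nBlocks)) {
    Wb <- W$enc[[i]]
    at <- .attnFwd(x, x, Wb$attn, mask, cfg@nHeads)
    d1 <- .dropFwd(at$out, cfg@dropout, training)
    l1 <- .lnFwd(x + d1$out, Wb$ln1$g, Wb$ln1$b)
    f1 <- .linFwd(l1$out, Wb$ffn$W1, Wb$ffn$b1)
    r  <- .reluFwd(f1$out)
    f2 <- .linFwd(r$out, Wb$ffn$W2, Wb$ffn$b2)
    d2 <- .dropFwd(f2$out, cfg@dropout, training)
    l2 <- .lnFwd(l1$out + d2$out, Wb$ln2$g, Wb$ln2$b)
    blocks[[i]] <- list(at = at, d1 = d1, l1 = l1, f1 = f1, r = r,
                        f2 = f2, d2 = d2, l2 = l2)
    x <- l2$out
  }
  list(h = x, cache = list(ed = ed, blocks = blocks, ids0 = ids0))
}

.encBwd <- function(dh, cache, W, cfg) {
  g <- list(emb = matrix(0, cfg@vocabSize, cfg@dModel),
            enc = vector("list", cfg@nBlocks))
  dx <- dh
  for (i in rev(seq_len(cfg@nBlocks))) {
    Wb <- W$enc[[i]]; cb <- cache$blocks[[i]]
    l2b <- .lnBwd(dx, cb$l2, Wb$ln2$g)
    dd2 <- .dropBwd(l2b$dx, cb$d2)
    f2b <- .linBwd(dd2, cb$f2, Wb$ffn$W2)
    drl <- .reluBwd(f2b$dx, cb$r)
    f1b <- .linBwd(drl, cb$f1, Wb$ffn$W1)
    dx1 <- l2b$dx + f1b$dx
    l1b <- .lnBwd(dx1, cb$l1, Wb$ln1$g)
    dd1 <- .dropBwd(l1b$dx, cb$d1)
    ab <- .attnBwd(dd1, cb$at, Wb$attn, cfg@nHeads)
    dx <- l1b$dx + ab$dXq + ab$dXkv
    g$enc[[i]] <- list(
      attn = list(Wq = ab$dWq, bq = ab$dbq, Wk = ab$dWk, bk = ab$dbk,
                  Wv = ab$dWv, bv = ab$dbv, Wo = ab$dWo, bo = ab$dbo),
      ln1 = list(g = l1b$dg, b = l1b$db),
      ffn = list(W1 = f1b$dW, b1 = f1b$db, W2 = f2b$dW, b2 = f2b$db),
      ln2 = list(g = l2b$dg, b = l2b$db))
  }
  dE <- .dropBwd(dx, cache$ed) * sqrt(cfg@dModel)
  ids <- cache$ids0 + 1L
  for (p in seq_along(ids))
    g$emb[ids[p], ] <- g$emb[ids[p], ] + dE[p, ]
  g
}

## ---- projection / unprojection -----------------------------------------

.projFwd <- function(W, cfg, h, padMask) {
  hz <- h
  hz[padMask, ] <- 0
  v <- matrix(as.numeric(t(hz)), 1L)
  layers <- vector("list", 4L)
  for (i in seq_len(4L)) {
    li <- .linFwd(v, W$proj[[i]]$W, W$proj[[i]]$b)
    ri <- .reluFwd(li$out)
    layers[[i]] <- list(lin = li, relu = ri)
    v <- ri$out
  }
  list(z = as.numeric(v), cache = list(layers = layers, padMask = padMask,
                                       L = nrow(h), D = ncol(h)))
}

.projBwd <- function(dz, cache, W, cfg) {
  dv <- matrix(dz, 1L)
  g <- vector("list", 4L)
  for (i in rev(seq_len(4L))) {
    dre <- .reluBwd(dv, cache$layers[[i]]$relu)
    lb <- .linBwd(dre, cache$layers[[i]]$lin, W$proj[[i]]$W)
    g[[i]] <- list(W = lb$dW, b = lb$db)
    dv <- lb$dx
  }
  dh <- matrix(as.numeric(dv), cache$L, cache$D, byrow = TRUE)
  dh[cache$padMask, ] <- 0
  list(dh = dh, proj = g)
}

.unprojFwd <- function(W, cfg, z) {
  v <- matrix(z, 1L)
  layers <- vector("list", 4L)
  for (i in seq_len(4L)) {
    li <- .linFwd(v, W$unproj[[i]]$W, W$unproj[[i]]$b)
    if (i < 4L) {
      ri <- .reluFwd(li$out)
      layers[[i]] <- list(lin = li, relu = ri)
      v <- ri$out
    } else {
      layers[[i]] <- list(lin = li)
      v <- li$out
    }
  }
  mem <- matrix(as.numeric(v), cfg@maxLen, cfg@dModel, byrow = TRUE)
  list(mem = mem, cache = list(layers = layers))
}

.unprojBwd <- function(dmem, cache, W, cfg) {
  dv <- matrix(as.numeric(t(dmem)), 1L)
  g <- vector("list", 4L)
  for (i in rev(seq_len(4L))) {
    if (i < 4L) dv <- .reluBwd(dv, cache$layers[[i]]$relu)
    lb <- .linBwd(dv, cache$layers[[i]]$lin, W$unproj[[i]]$W)
    g[[i]] <- list(W = lb$dW, b = lb$db)
    dv <- lb$dx
  }
  list(dz = as.numeric(dv), unproj = g)
}

## ---- decoder ------------------------------------------------------------

.decFwd <- function(W, cfg, ids0, padMask, mem, training = FALSE) {
  L <- length(ids0); D <- cfg@dModel
  E <- W$emb[ids0 + 1L, , drop = FALSE] * sqrt(D) +
    .pe(cfg@maxLen, D)[seq_len(L), , drop = FALSE]
  ed <- .dropFwd(E, cfg@dropout, training)
  x <- ed$out
  keyOK <- !padMask
  causal <- outer(seq_len(L), seq_len(L), ">=") &
    matrix(keyOK, L, L, byrow = TRUE)
  crossMask <- matrix(TRUE, L, nrow(mem))
  blocks <- vector("list", cfg@nBlocks)
  for (i in seq_len(cfg@nBlocks)) {
    Wb <- W$dec[[i]]
    a1 <- .attnFwd(x, x, Wb$self, causal, cfg@nHeads)
    d1 <- .dropFwd(a1$out, cfg@dropout, training)
    l1 <- .lnFwd(x + d1$out, Wb$ln1$g, Wb$ln1$b)
    a2 <- .attnFwd(l1$out, mem, Wb$cross, crossMask, cfg@nHeads)
    d2 <- .dropFwd(a2$out, cfg@dropout, training)
    l2 <- .lnFwd(l1$out + d2$out, Wb$ln2$g, Wb$ln2$b)
    f1 <- .linFwd(l2$out, Wb$ffn$W1, Wb$ffn$b1)
    r  <- .reluFwd(f1$out)
    f2 <- .linFwd(r$out, Wb$ffn$W2, Wb$ffn$b2)
    d3 <- .dropFwd(f2$out, cfg@dropout, training)
    l3 <- .lnFwd(l2$out + d3$out, Wb$ln3$g, Wb$ln3$b)
    blocks[[i]] <- list(a1 = a1, d1 = d1, l1 = l1, a2 = a2, d2 = d2,
                        l2 = l2, f1 = f1, r = r, f2 = f2, d3 = d3, l3 = l3)
    x <- l3$out
  }
  ol <- .linFwd(x, W$out$W, W$out$b)
  probs <- .softmaxRows(ol$out)
  list(probs = probs, logits = ol$out,
       cache = list(ed = ed, blocks = blocks, ol = ol, ids0 = ids0,
                    memRows = nrow(mem)))
}

# dlogits: gradient at the pre-softmax logits (softmax+CE combined upstream)
.decBwd <- function(dlogits, cache, W, cfg) {
  g <- list(emb = matrix(0, cfg@vocabSize, cfg@dModel),
            dec = vector("list", cfg@nBlocks),
            out = NULL)
  ob <- .linBwd(dlogits, cache$ol, W$out$W)
  g$out <- list(W = ob$dW, b = ob$db)
  dx <- ob$dx
  dmem <- matrix(0, cache$memRows, cfg@dModel)
  for (i in rev(seq_len(cfg@nBlocks))) {
    Wb <- W$dec[[i]]; cb <- cache$blocks[[i]]
    l3b <- .lnBwd(dx, cb$l3, Wb$ln3$g)
    dd3 <- .dropBwd(l3b$dx, cb$d3)
    f2b <- .linBwd(dd3, cb$f2, Wb$ffn$W2)
    drl <- .reluBwd(f2b$dx, cb$r)
    f1b <- .linBwd(drl, cb$f1, Wb$ffn$W1)
    dx2 <- l3b$dx + f1b$dx
    l2b <- .lnBwd(dx2, cb$l2, Wb$ln2$g)
    dd2 <- .dropBwd(l2b$dx, cb$d2)
    a2b <- .attnBwd(dd2, cb$a2, Wb$cross, cfg@nHeads)
    dmem <- dmem + a2b$dXkv
    dx1 <- l2b$dx + a2b$dXq
    l1b <- .lnBwd(dx1, cb$l1, Wb$ln1$g)
    dd1 <- .dropBwd(l1b$dx, cb$d1)
    a1b <- .attnBwd(dd1, cb$a1, Wb$self, cfg@nHeads)
    dx <- l1b$dx + a1b$dXq + a1b$dXkv
    g$dec[[i]] <- list(
      self = list(Wq = a1b$dWq, bq = a1b$dbq, Wk = a1b$dWk, bk = a1b$dbk,
                  Wv = a1b$dWv, bv = a1b$dbv, Wo = a1b$dWo, bo = a1b$dbo),
      ln1 = list(g = l1b$dg, b = l1b$db),
      cross = list(Wq = a2b$dWq, bq = a2b$dbq, Wk = a2b$dWk, bk = a2b$dbk,
                   Wv = a2b$dWv, bv = a2b$dbv, Wo = a2b$dWo, bo = a2b$dbo),
      ln2 = list(g = l2b$dg, b = l2b$db),
      ffn = list(W1 = f1b$dW, b1 = f1b$db, W2 = f2b$dW, b2 = f2b$db),
      ln3 = list(g = l3b$dg, b = l3b$db))
  }
  dE <- .dropBwd(dx, cache$ed) * sqrt(cfg@dModel)
  ids <- cache$ids0 + 1L
  for (p in seq_along(ids))
    g$emb[ids[p], ] <- g$emb[ids[p], ] + dE[p, ]
  list(grads = g, dmem = dmem)
}

## ---- exported forward API ----------------------------------------------

#' Encode a SMILES string into its representation h
#'
#' Runs embedding + positional encoding through the transformer encoder in
#' evaluation mode (no dropout). Padding positions are excluded from
#' attention, so the non-pad rows of h do not depend on the amount of
#' padding.
#'
#' @param model a [FragNetModel-class]
#' @param smiles a single SMILES string
#' @param oov out-of-vocabulary handling, see [encodeSequence()]
#' @return maxLen x dModel matrix with attribute \code{padMask}
#' @export
fragnetEncode <- function(model, smiles, oov = "unk") {
  cfg <- model@config
  es <- encodeSequence(smiles, model@vocabulary, cfg@maxLen, oov = oov)
  f <- .encFwd(model@weights, cfg, es$tokenIds, es$padMask)
  structure(f$h, padMask = es$padMask, smiles = smiles)
}

#' Project a representation to the latent vector z
#'
#' Zeroes the padding rows of h, flattens it and applies the 4-layer
#' projection head; every layer (the last included) is followed by a ReLU,
#' so latent entries are non-negative and can be exactly zero.
#'
#' @param model a [FragNetModel-class]
#' @param h representation from [fragnetEncode()] (its \code{padMask}
#'   attribute is used; a bare matrix is treated as having no padding)
#' @return numeric latent vector of length dModel
#' @export
fragnetProject <- function(model, h) {
  pm <- attr(h, "padMask")
  if (is.null(pm)) pm <- rep(FALSE, nrow(h))
  .projFwd(model@weights, model@config, h, pm)$z
}

#' Map a latent vector back to a decoder memory
#'
#' The unprojection head mirrors the projection head (three ReLU layers,
#' final layer linear so the memory is not sign-restricted) and reshapes
#' the output to maxLen x dModel; the decoder's cross attention reads its
#' keys and values from this matrix.
#'
#' @param model a [FragNetModel-class]
#' @param z latent vector of length dModel
#' @return maxLen x dModel memory matrix
#' @export
fragnetUnproject <- function(model, z) {
  stopifnot(length(z) == model@config@dModel)
  .unprojFwd(model@weights, model@config, z)$mem
}

#' Teacher-forced decoder probabilities
#'
#' Runs the masked transformer decoder over the shifted-right target
#' sequence with cross attention on \code{memory} and returns the
#' per-position next-token probability rows (each row sums to 1). The
#' causal mask guarantees position t depends only on targets at positions
#' <= t.
#'
#' @param model a [FragNetModel-class]
#' @param memory decoder memory from [fragnetUnproject()]
#' @param targets an encoded sequence from [encodeSequence()] (starts with
#'   the start token), or a SMILES string to encode
#' @return maxLen x vocabSize matrix of probabilities
#' @export
fragnetDecode <- function(model, memory, targets) {
  cfg <- model@config
  if (is.character(targets))
    targets <- encodeSequence(targets, model@vocabulary, cfg@maxLen)
  stopifnot(targets$tokenIds[1L] == 1L)
  .decFwd(model@weights, cfg, targets$tokenIds, targets$padMask,
          memory)$probs
}

#' Greedy autoregressive decoding of a latent vector
#'
#' Starting from the start token, repeatedly feeds the grown prefix to the
#' decoder and appends the argmax token, stopping at the first end token or
#' at maxLen. Returns the concatenated chemical tokens (specials dropped);
#' the result is not guaranteed to be a valid SMILES and callers should
#' validate it.
#'
#' @param model a [FragNetModel-class]
#' @param z latent vector of length dModel
#' @return character string (at most maxLen - 2 tokens)
#' @export
greedyDecode <- function(model, z) {
  cfg <- model@config
  mem <- .unprojFwd(model@weights, cfg, z)$mem
  ids <- 1L                                   # <s>
  while (length(ids) < cfg@maxLen) {
    f <- .decFwd(model@weights, cfg, ids, rep(FALSE, length(ids)), mem)
    nxt <- which.max(f$probs[length(ids), ]) - 1L
    if (nxt == 2L) break                      # </s>
    ids <- c(ids, nxt)
  }
  decodeSequence(ids, model@vocabulary)
}

#' Encode, project and greedily reconstruct a molecule
#'
#' Convenience round trip decode(project(encode(x))) used to probe
#' memorization: a model overfit on a tiny corpus should reproduce its
#' training molecules exactly.
#'
#' @param model a [FragNetModel-class]
#' @param smiles SMILES string
#' @return the greedily decoded string
#' @export
roundTripDecode <- function(model, smiles) {
  h <- fragnetEncode(model, smiles)
  greedyDecode(model, fragnetProject(model, h))
}
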