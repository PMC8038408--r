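# Joint contrastive + reconstruction training. Each step draws a fresh
# enumerated positive pair per molecule (canonical strings never enter
# training), encodes and projects the 2N views with shared weights, applies
# NT-Xent over the 2N latents, reconstructs every view from its own latent
# through the unprojection head and masked decoder, and takes one Adam step
# on the weighted sum of the two losses.

#' Split a corpus into training and validation sets
#'
#' Seeded random shuffle, then the first \code{floor(trainFraction * n)}
#' records become the training set; the split is disjoint and exhaustive.
#' The published regime uses a 3:2 ratio for the small corpus and
#' 125,000/25,000 for the large one.
#'
#' @param records molecule records (data.frame)
#' @param trainFraction fraction in (0, 1)
#' @param seed optional shuffle seed (caller RNG restored)
#' @return list with \code{train} and \code{validation} data.frames
#' @export
splitDataset <- function(records, trainFraction, seed = NULL) {
  n <- nrow(records)
  if (is.null(n) || n == 0L) stop("empty corpus")
  if (trainFraction <= 0 || trainFraction >= 1)
    stop("trainFraction must be in (0, 1)")
  idx <- .withSeed(seed, sample.int(n))
  k <- floor(trainFraction * n)
  list(train = records[utils::head(idx, k), , drop = FALSE],
       validation = records[utils::tail(idx, n - k), , drop = FALSE])
}

#' Shuffle a corpus into contrastive batches
#'
#' With \code{dropLast} (the default) only complete batches are returned,
#' i.e. \code{floor(n / batchSize)} of them, matching the published batch
#' counts (4,643 molecules at batch size 50 give 92 batches; 150,000 at
#' batch size 20 give 7,500).
#'
#' @param records molecule records (data.frame)
#' @param batchSize molecules per batch; must be >= 2 because the
#'   contrastive loss needs at least one negative
#' @param dropLast drop the trailing incomplete batch
#' @param seed optional shuffle seed (caller RNG restored)
#' @return list of data.frames
#' @export
makeBatches <- function(records, batchSize, dropLast = TRUE, seed = NULL) {
  if (batchSize < 2L) stop("batchSize must be >= 2")
  n <- nrow(records)
  idx <- .withSeed(seed, sample.int(n))
  nb <- if (dropLast) floor(n / batchSize) else ceiling(n / batchSize)
  lapply(seq_len(nb), function(b) {
    lo <- (b - 1L) * batchSize + 1L
    hi <- min(b * batchSize, n)
    records[idx[lo:hi], , drop = FALSE]
  })
}

## ---- flat parameter vector + Adam --------------------------------------

.flatW <- function(w) unlist(w, use.names = FALSE)

.unflatW <- function(vec, tmpl) {
  pos <- 0L
  rec <- function(t) {
    if (is.list(t)) return(lapply(t, rec))
    n <- length(t)
    out <- vec[(pos + 1L):(pos + n)]
    pos <<- pos + n
    if (!is.null(dim(t))) dim(out) <- dim(t)
    out
  }
  rec(tmpl)
}

.adamInit <- function(nPar) list(t = 0L, m = numeric(nPar), v = numeric(nPar))

.adamStep <- function(w, g, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  st$m <- beta1 * st$m + (1 - beta1) * g
  st$v <- beta2 * st$v + (1 - beta2) * g * g
  mhat <- st$m / (1 - beta1^st$t)
  vhat <- st$v / (1 - beta2^st$t)
  list(w = w - lr * mhat / (sqrt(vhat) + eps), state = st)
}

# accumulate partial nested gradients into the same-shape accumulator
.addG <- function(a, b) {
  if (is.null(b)) return(a)
  if (is.list(a)) {
    for (i in seq_along(b)) if (!is.null(b[[i]]))
      a[[i]] <- .addG(a[[i]], b[[i]])
    a
  } else a + b
}

.zeroLike <- function(w) {
  if (is.list(w)) lapply(w, .zeroLike) else w * 0
}

## ---- one optimisation step ---------------------------------------------

# views: list of encoded sequences (length 2N, pair-adjacent ordering)
.stepForwardBackward <- function(W, cfg, views, training = TRUE) {
  n2 <- length(views)
  encs <- vector("list", n2); projs <- vector("list", n2)
  Z <- matrix(0, n2, cfg@dModel)
  for (v in seq_len(n2)) {
    encs[[v]] <- .encFwd(W, cfg, views[[v]]$tokenIds, views[[v]]$padMask,
                         training)
    projs[[v]] <- .projFwd(W, cfg, encs[[v]]$h, views[[v]]$padMask)
    Z[v, ] <- projs[[v]]$z
  }
  ntx <- ntXent(Z, cfg@temperature, grad = TRUE)
  grads <- .zeroLike(W)
  recLosses <- numeric(n2)
  for (v in seq_len(n2)) {
    up <- .unprojFwd(W, cfg, Z[v, ])
    dec <- .decFwd(W, cfg, views[[v]]$tokenIds, views[[v]]$padMask,
                   up$mem, training)
    recLosses[v] <- reconstructionLoss(dec$probs, views[[v]])
    dlog <- .recGrad(dec$probs, views[[v]]) * (cfg@reconWeight / n2)
    db <- .decBwd(dlog, dec$cache, W, cfg)
    grads$emb <- grads$emb + db$grads$emb
    grads$dec <- .addG(grads$dec, db$grads$dec)
    grads$out <- .addG(grads$out, db$grads$out)
    ub <- .unprojBwd(db$dmem, up$cache, W, cfg)
    grads$unproj <- .addG(grads$unproj, ub$unproj)
    dz <- cfg@contrastiveWeight * ntx$dz[v, ] + ub$dz
    pb <- .projBwd(dz, projs[[v]]$cache, W, cfg)
    grads$proj <- .addG(grads$proj, pb$proj)
    eb <- .encBwd(pb$dh, encs[[v]]$cache, W, cfg)
    grads$emb <- grads$emb + eb$emb
    grads$enc <- .addG(grads$enc, eb$enc)
  }
  list(grads = grads, contrastive = ntx$loss,
       reconstruction = mean(recLosses),
       total = totalLoss(ntx$loss, mean(recLosses), cfg))
}

#' One training step on a batch of molecules
#'
#' Draws an enumerated positive pair per record, runs the full forward and
#' backward pass over the 2N views and applies one Adam update. Exposed
#' mainly for instrumentation; [trainFragNet()] is the user entry point.
#'
#' @param batch molecule records (N rows, N >= 2)
#' @param model a [FragNetModel-class]
#' @param optState Adam state from a previous call, or NULL to start
#' @param augment draw fresh enumerated views (the production regime);
#'   \code{FALSE} feeds each record's own string as both views, the
#'   overfitting probe used to verify the autoencoder path can memorize
#' @return list with the updated \code{model}, \code{optState},
#'   \code{losses} (contrastive, reconstruction, total) and \code{inputs}
#'   (the 2N SMILES consumed; under augmentation never the canonical
#'   strings)
#' @export
trainStep <- function(batch, model, optState = NULL, augment = TRUE) {
  cfg <- model@config
  if (nrow(batch) < 2L) stop("contrastive batch needs at least 2 molecules")
  views <- list(); inputs <- character(0)
  for (r in seq_len(nrow(batch))) {
    pair <- if (augment) samplePositivePair(batch[r, ]) else
      list(x_i = batch$smiles[r], x_j = batch$smiles[r])
    inputs <- c(inputs, pair$x_i, pair$x_j)
    views <- c(views,
               list(encodeSequence(pair$x_i, model@vocabulary, cfg@maxLen),
                    encodeSequence(pair$x_j, model@vocabulary, cfg@maxLen)))
  }
  fb <- .stepForwardBackward(model@weights, cfg, views, training = TRUE)
  if (!all(is.finite(c(fb$contrastive, fb$reconstruction))))
    stop("non-finite loss (contrastive=", fb$contrastive,
         ", reconstruction=", fb$reconstruction, ") at Adam step ",
         if (is.null(optState)) 1L else optState$t + 1L)
  wflat <- .flatW(model@weights)
  gflat <- .flatW(fb$grads)
  if (is.null(optState)) optState <- .adamInit(length(wflat))
  upd <- .adamStep(wflat, gflat, optState, cfg@learningRate)
  model@weights <- .unflatW(upd$w, model@weights)
  list(model = model, optState = upd$state,
       losses = c(contrastive = fb$contrastive,
                  reconstruction = fb$reconstruction, total = fb$total),
       inputs = inputs)
}

#' Train the contrastive transformer autoencoder
#'
#' Runs \code{config@epochs} passes (default 1: the model is effectively a
#' one-shot learner) over shuffled complete batches, drawing fresh
#' enumerated augmentations every batch. Canonical SMILES never enter
#' training; they are used only later, to obtain projection vectors. The
#' master seed fans out to weight initialisation and to the
#' shuffle/augmentation/dropout stream.
#'
#' @param records training molecule records
#' @param config a [FragNetConfig-class] (its \code{vocabSize} must match
#'   the vocabulary)
#' @param vocabulary a [TokenVocabulary-class]; built from \code{records}
#'   when omitted
#' @param maxSteps optional cap on the number of Adam steps
#' @param augment see [trainStep()]; keep the default outside of
#'   memorization probes
#' @param trace keep the augmented input strings of every step (for
#'   instrumentation; memory grows with steps)
#' @param verbose print per-batch losses
#' @return list with \code{model} (a [FragNetModel-class]), \code{metrics}
#'   (data.frame: epoch, batch, contrastive, reconstruction, total) and,
#'   when \code{trace = TRUE}, \code{inputs}
#' @export
trainFragNet <- function(records, config, vocabulary = NULL,
                         maxSteps = Inf, augment = TRUE, trace = FALSE,
                         verbose = FALSE) {
  if (nrow(records) == 0L) stop("empty corpus")
  if (is.null(vocabulary))
    vocabulary <- buildVocabulary(records, seed = config@seed)
  if (config@vocabSize != vocabSize(vocabulary))
    stop("config@vocabSize (", config@vocabSize,
         ") does not match vocabulary size (", vocabSize(vocabulary), ")")
  set.seed(config@seed)
  seeds <- sample.int(.Machine$integer.max, 2L)
  cfgInit <- config; cfgInit@seed <- seeds[1L]
  model <- fragnetInit(cfgInit, vocabulary)
  model@config <- config
  set.seed(seeds[2L])
  optState <- NULL
  rows <- list(); allInputs <- character(0)
  step <- 0L
  for (ep in seq_len(config@epochs)) {
    batches <- makeBatches(records, config@batchSize, dropLast = TRUE)
    for (b in seq_along(batches)) {
      if (step >= maxSteps) break
      st <- trainStep(batches[[b]], model, optState, augment = augment)
      model <- st$model; optState <- st$optState
      step <- step + 1L
      rows[[step]] <- data.frame(epoch = ep, batch = b,
                                 contrastive = st$losses[["contrastive"]],
                                 reconstruction =
                                   st$losses[["reconstruction"]],
                                 total = st$losses[["total"]])
      if (trace) allInputs <- c(allInputs, st$inputs)
      if (verbose)
        message(sprintf("epoch %d batch %d  con %.4f  rec %.4f  tot %.4f",
                        ep, b, st$losses[["contrastive"]],
                        st$losses[["reconstruction"]],
                        st$losses[["total"]]))
    }
    if (step >= maxSteps) break
  }
  out <- list(model = model, metrics = do.call(rbind, rows))
  if (trace) out$inputs <- allInputs
  out
}

## ---- checkpoints --------------------------------------------------------

.serW <- function(w) {
  if (is.list(w)) lapply(w, .serW)
  else list(.dim = if (is.null(dim(w))) length(w) else dim(w),
            .v = as.numeric(w))
}
.deserW <- function(s) {
  if (!is.null(s$.v)) {
    v <- as.numeric(unlist(s$.v))
    d <- as.integer(unlist(s$.dim))
    if (length(d) > 1L) dim(v) <- d
    return(v)
  }
  lapply(s, .deserW)
}

#' Save a model checkpoint
#'
#' A single JSON file holding the weights at full precision, the complete
#' configuration and the vocabulary with its hash; [loadCheckpoint()]
#' verifies the hash.
#'
#' @param model a [FragNetModel-class]
#' @param path output path
#' @return invisibly, the path
#' @export
saveCheckpoint <- function(model, path) {
  cfg <- model@config
  obj <- list(
    format = "fragnet-checkpoint-1",
    config = sapply(slotNames(cfg), function(s) slot(cfg, s),
                    simplify = FALSE),
    tokens = model@vocabulary@tokens,
    vocabHash = model@vocabHash,
    weights = .serW(model@weights))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17)), path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path path written by [saveCheckpoint()]
#' @return a [FragNetModel-class]
#' @export
loadCheckpoint <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(obj$format, "fragnet-checkpoint-1"))
    stop("not a fragnet checkpoint: ", path)
  vocab <- new("TokenVocabulary", tokens = unlist(obj$tokens))
  if (!identical(.vocabHash(vocab), obj$vocabHash))
    stop("vocabulary hash mismatch in checkpoint ", path)
  cfgArgs <- lapply(obj$config, unlist)
  cfg <- do.call(fragnetConfig, cfgArgs[setdiff(names(cfgArgs), NULL)])
  new("FragNetModel", config = cfg, vocabulary = vocab,
      weights = .deserW(obj$weights), vocabHash = obj$vocabHash)
}
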