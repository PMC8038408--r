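#' @import methods
NULL

#' Model and training configuration
#'
#' Holds every architecture and training hyperparameter of the contrastive
#' transformer autoencoder: the latent/embedding width \code{dModel}, the
#' number of transformer blocks and attention heads, the padded sequence
#' length, dropout rate, the NT-Xent temperature \eqn{\tau}, batch size,
#' learning rate, the feed-forward width, the three hidden widths of the
#' 4-layer projection head, and the weights mixing the contrastive and
#' reconstruction objectives.
#'
#' @slot dModel latent and embedding width (must be divisible by \code{nHeads})
#' @slot nBlocks number of encoder blocks and of decoder blocks
#' @slot nHeads attention heads per multi-head attention layer
#' @slot maxLen padded token-sequence length (including start/end tokens)
#' @slot vocabSize vocabulary size (specials included)
#' @slot dropout dropout fraction applied to embeddings and sublayer outputs
#' @slot temperature NT-Xent temperature \eqn{\tau > 0}
#' @slot batchSize number of molecules N per contrastive batch (2N views)
#' @slot learningRate Adam learning rate
#' @slot ffDim position-wise feed-forward hidden width
#' @slot projHidden integer(3): hidden widths of the 4-layer projection head
#' @slot reconWeight weight of the reconstruction cross-entropy term
#' @slot contrastiveWeight weight of the NT-Xent term
#' @slot epochs number of passes over the training set
#' @slot seed master seed fanned out to split/shuffle/augmentation/init streams
#' @seealso [fragnetConfig()]
#' @exportClass FragNetConfig
setClass("FragNetConfig",
  representation(
    dModel = "integer", nBlocks = "integer", nHeads = "integer",
    maxLen = "integer", vocabSize = "integer",
    dropout = "numeric", temperature = "numeric",
    batchSize = "integer", learningRate = "numeric",
    ffDim = "integer", projHidden = "integer",
    reconWeight = "numeric", contrastiveWeight = "numeric",
    epochs = "integer", seed = "integer"
  )
)

setValidity("FragNetConfig", function(object) {
  msg <- character()
  if (object@dModel < 2L) msg <- c(msg, "dModel must be >= 2")
  if (object@dModel %% 2L != 0L) msg <- c(msg, "dModel must be even")
  if (object@dModel %% object@nHeads != 0L)
    msg <- c(msg, "dModel must be divisible by nHeads")
  if (object@temperature <= 0) msg <- c(msg, "temperature must be > 0")
  if (object@dropout < 0 || object@dropout >= 1)
    msg <- c(msg, "dropout must be in [0, 1)")
  if (length(object@projHidden) != 3L)
    msg <- c(msg, "projHidden must have exactly 3 entries (4 layers)")
  if (object@maxLen < 3L) msg <- c(msg, "maxLen must be >= 3")
  if (object@batchSize < 2L) msg <- c(msg, "batchSize must be >= 2")
  if (object@reconWeight < 0 || object@contrastiveWeight < 0)
    msg <- c(msg, "loss weights must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Create a FragNetConfig
#'
#' Defaults follow the published training regime of the method: 4 encoder
#' and 4 decoder blocks with 4 attention heads each, 20% dropout, Adam with
#' learning rate 1e-5, temperature 0.05, and a single epoch (the model is
#' effectively a one-shot learner). \code{ffDim} defaults to
#' \code{4 * dModel} and the projection-head hidden widths to a geometric
#' taper \code{c(4, 2, 1) * dModel}.
#'
#' @param vocabSize vocabulary size; usually \code{vocabSize(vocab)}
#' @param maxLen padded sequence length
#' @param dModel latent width
#' @param nBlocks,nHeads transformer depth and heads
#' @param dropout dropout fraction
#' @param temperature NT-Xent temperature
#' @param batchSize molecules per batch
#' @param learningRate Adam learning rate
#' @param ffDim feed-forward width
#' @param projHidden hidden widths of the projection head (length 3)
#' @param reconWeight,contrastiveWeight loss mixing weights
#' @param epochs training epochs
#' @param seed master seed
#' @return a [FragNetConfig-class] object
#' @examples
#' cfg <- fragnetConfig(vocabSize = 30L, maxLen = 24L, dModel = 32L)
#' cfg
#' @export
fragnetConfig <- function(vocabSize, maxLen = 450L, dModel = 64L,
                          nBlocks = 4L, nHeads = 4L, dropout = 0.2,
                          temperature = 0.05, batchSize = 40L,
                          learningRate = 1e-5, ffDim = 4L * dModel,
                          projHidden = c(4L, 2L, 1L) * dModel,
                          reconWeight = 1.0, contrastiveWeight = 1.0,
                          epochs = 1L, seed = 42L) {
  new("FragNetConfig",
      dModel = as.integer(dModel), nBlocks = as.integer(nBlocks),
      nHeads = as.integer(nHeads), maxLen = as.integer(maxLen),
      vocabSize = as.integer(vocabSize), dropout = as.numeric(dropout),
      temperature = as.numeric(temperature),
      batchSize = as.integer(batchSize),
      learningRate = as.numeric(learningRate), ffDim = as.integer(ffDim),
      projHidden = as.integer(projHidden),
      reconWeight = as.numeric(reconWeight),
      contrastiveWeight = as.numeric(contrastiveWeight),
      epochs = as.integer(epochs), seed = as.integer(seed))
}

#' @exportMethod show
#' @noRd
setMethod("show", "FragNetConfig", function(object) {
  cat("FragNetConfig\n")
  cat(sprintf("  dModel=%d  blocks=%d  heads=%d  maxLen=%d  vocab=%d\n",
              object@dModel, object@nBlocks, object@nHeads,
              object@maxLen, object@vocabSize))
  cat(sprintf("  tau=%g  batch=%d  lr=%g  dropout=%g  epochs=%d  seed=%d\n",
              object@temperature, object@batchSize, object@learningRate,
              object@dropout, object@epochs, object@seed))
})

#' Token vocabulary over SMILES tokens
#'
#' Index 0 is the pad token, 1 the start token, 2 the end token and 3 the
#' unknown token; chemical tokens follow in lexicographic (C-locale) order.
#' All token indices in the package are 0-based to honour this contract;
#' they are shifted internally when used as R matrix rows.
#'
#' @slot tokens character vector; position \code{i} holds the token with
#'   index \code{i - 1}
#' @seealso [buildVocabulary()], [tokenIndex()], [vocabSize()]
#' @exportClass TokenVocabulary
setClass("TokenVocabulary", representation(tokens = "character"))

.SPECIALS <- c("<pad>", "<s>", "</s>", "<unk>")

setValidity("TokenVocabulary", function(object) {
  msg <- character()
  if (length(object@tokens) < 4L ||
      !identical(object@tokens[1:4], .SPECIALS))
    msg <- c(msg, "first four tokens must be <pad>, <s>, </s>, <unk>")
  if (anyDuplicated(object@tokens)) msg <- c(msg, "duplicate tokens")
  if (length(msg)) msg else TRUE
})

#' @describeIn TokenVocabulary-class number of tokens (specials included)
#' @param vocab a \code{TokenVocabulary}
#' @export
vocabSize <- function(vocab) length(vocab@tokens)

#' 0-based index of a token
#'
#' @param vocab a [TokenVocabulary-class]
#' @param token character vector of tokens
#' @return integer vector of 0-based indices; unknown tokens map to the
#'   unknown-token index 3
#' @export
tokenIndex <- function(vocab, token) {
  idx <- match(token, vocab@tokens)
  idx[is.na(idx)] <- 4L
  idx - 1L
}

#' @exportMethod show
#' @noRd
setMethod("show", "TokenVocabulary", function(object) {
  cat(sprintf("TokenVocabulary of %d tokens (4 specials + %d chemical)\n",
              length(object@tokens), length(object@tokens) - 4L))
  chem <- setdiff(object@tokens, .SPECIALS)
  cat("  ", paste(utils::head(chem, 15), collapse = " "),
      if (length(chem) > 15) "..." else "", "\n")
})

#' Trained (or initialised) contrastive transformer autoencoder
#'
#' Bundles the weights of the full architecture (token embedding, encoder
#' blocks, projection head, unprojection head, decoder blocks, output
#' layer), its configuration and its vocabulary. The vocabulary hash is
#' stored in checkpoints and verified on load.
#'
#' @slot config a [FragNetConfig-class]
#' @slot vocabulary a [TokenVocabulary-class]
#' @slot weights named list of weight matrices/vectors
#' @slot vocabHash hash of the vocabulary token list
#' @seealso [fragnetInit()], [trainFragNet()], [saveCheckpoint()]
#' @exportClass FragNetModel
setClass("FragNetModel",
  representation(config = "FragNetConfig", vocabulary = "TokenVocabulary",
                 weights = "list", vocabHash = "character"))

setValidity("FragNetModel", function(object) {
  if (object@config@vocabSize != vocabSize(object@vocabulary))
    return("config vocabSize does not match vocabulary size")
  TRUE
})

#' @describeIn FragNetModel-class configuration accessor
#' @param model a \code{FragNetModel}
#' @export
modelConfig <- function(model) model@config

#' @describeIn FragNetModel-class vocabulary accessor
#' @export
modelVocabulary <- function(model) model@vocabulary

#' @exportMethod show
#' @noRd
setMethod("show", "FragNetModel", function(object) {
  np <- sum(vapply(object@weights, function(w) {
    if (is.list(w)) sum(vapply(rapply(w, length, how = "unlist"),
                               identity, numeric(1)))
    else length(w)
  }, numeric(1)))
  cat("FragNetModel\n")
  show(object@config)
  cat(sprintf("  parameters: %s\n", format(np, big.mark = ",")))
})

#' Matrix of latent projection vectors
#'
#' One row per molecule: the pooled projection vector z produced by the
#' encoder + projection head from the canonical SMILES in evaluation mode.
#' Entries are non-negative because the projection head ends in a ReLU.
#'
#' @slot ids unique molecule identifiers (row order)
#' @slot vectors numeric matrix, n x dModel
#' @slot sourceTemperature temperature of the producing model
#' @seealso [embedCorpus()], [dimensionPopulation()], [neighborQuery()]
#' @exportClass LatentMatrix
setClass("LatentMatrix",
  representation(ids = "character", vectors = "matrix",
                 sourceTemperature = "numeric"))

setValidity("LatentMatrix", function(object) {
  msg <- character()
  if (length(object@ids) != nrow(object@vectors))
    msg <- c(msg, "ids length must equal number of rows")
  if (anyDuplicated(object@ids)) msg <- c(msg, "ids must be unique")
  if (!all(is.finite(object@vectors))) msg <- c(msg, "non-finite entries")
  if (length(msg)) msg else TRUE
})

#' Construct a LatentMatrix
#' @param ids character vector of unique ids
#' @param vectors numeric matrix with one row per id
#' @param sourceTemperature temperature of the model that produced the
#'   vectors (NA when unknown)
#' @return a [LatentMatrix-class]
#' @export
latentMatrix <- function(ids, vectors, sourceTemperature = NA_real_) {
  new("LatentMatrix", ids = as.character(ids),
      vectors = as.matrix(vectors),
      sourceTemperature = as.numeric(sourceTemperature))
}

#' @describeIn LatentMatrix-class ids accessor
#' @param x a \code{LatentMatrix}
#' @export
latentIds <- function(x) x@ids

#' @describeIn LatentMatrix-class matrix accessor (rows named by id)
#' @export
latentVectors <- function(x) {
  v <- x@vectors
  rownames(v) <- x@ids
  v
}

#' @exportMethod dim
#' @noRd
setMethod("dim", "LatentMatrix", function(x) dim(x@vectors))

#' @exportMethod show
#' @noRd
setMethod("show", "LatentMatrix", function(object) {
  cat(sprintf("LatentMatrix: %d molecules x %d dimensions (tau=%s)\n",
              nrow(object@vectors), ncol(object@vectors),
              format(object@sourceTemperature)))
})
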