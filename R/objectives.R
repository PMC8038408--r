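# The two training objectives: the NT-Xent contrastive loss over the 2N
# latent vectors of a batch (temperature-scaled softmax over cosine
# similarities, positives = the two enumerated views of one molecule) and
# the masked cross-entropy reconstruction loss of the decoder.

#' Cosine similarity
#'
#' \code{dot(a, b) / (|a| |b|)}. A zero vector has no direction; its
#' similarity to anything is defined as 0 (possible here because the
#' projection head ends in a ReLU) and a warning is raised.
#'
#' @param a,b numeric vectors of equal length
#' @return similarity in [-1, 1]
#' @export
cosineSim <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) {
    warning("cosineSim: zero vector; similarity defined as 0")
    return(0)
  }
  sum(a * b) / (na * nb)
}

# rows of Z normalized to unit length; zero rows stay zero
.unitRows <- function(Z) {
  n <- sqrt(rowSums(Z * Z))
  U <- Z / ifelse(n > 0, n, 1)
  list(U = U, norms = n)
}

#' NT-Xent contrastive loss
#'
#' The normalized temperature-scaled cross entropy over a batch of 2N
#' latent vectors ordered so rows (2k-1, 2k) are the positive pair of
#' molecule k. For anchor i with positive j the per-anchor term is
#' \deqn{-\log \frac{\exp(sim(z_i, z_j)/\tau)}
#'                  {\sum_{k \ne i} \exp(sim(z_i, z_k)/\tau)}}
#' with cosine similarity as sim(); the returned value is the mean over
#' all 2N anchors. Exponentials are max-stabilised. Zero vectors enter
#' with similarity 0 (warning).
#'
#' @param z numeric matrix 2N x d (2N even, >= 4) of projection vectors
#' @param temperature positive temperature \eqn{\tau}
#' @param grad also return the gradient with respect to \code{z}
#' @return the scalar loss, or (with \code{grad = TRUE}) a list with
#'   \code{loss} and \code{dz}
#' @examples
#' z <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
#' ntXent(z, temperature = 1)   # log(1 + 2 * exp(-1))
#' @export
ntXent <- function(z, temperature, grad = FALSE) {
  if (temperature <= 0) stop("temperature must be > 0")
  z <- as.matrix(z)
  n2 <- nrow(z)
  if (n2 < 4L || n2 %% 2L != 0L)
    stop("batch must hold an even number >= 4 of vectors")
  if (any(sqrt(rowSums(z * z)) == 0))
    warning("ntXent: zero latent vector(s); their similarities are 0")
  un <- .unitRows(z)
  C <- tcrossprod(un$U)
  pos <- ifelse(seq_len(n2) %% 2L == 1L, seq_len(n2) + 1L, seq_len(n2) - 1L)
  S <- C / temperature
  diag(S) <- -Inf                        # k != i indicator
  m <- apply(S, 1L, max)
  E <- exp(S - m)
  denom <- rowSums(E)
  loss_i <- -(S[cbind(seq_len(n2), pos)] - m - log(denom))
  loss <- mean(loss_i)
  if (!grad) return(loss)
  P <- E / denom                         # softmax over k != i (diag 0)
  G <- P
  G[cbind(seq_len(n2), pos)] <- G[cbind(seq_len(n2), pos)] - 1
  G <- G / (n2 * temperature)            # dL/dC, diag 0
  dU <- (G + t(G)) %*% un$U
  rs <- rowSums(dU * un$U)
  dz <- (dU - un$U * rs) / ifelse(un$norms > 0, un$norms, 1)
  dz[un$norms == 0, ] <- 0
  list(loss = loss, dz = dz)
}

#' Masked reconstruction cross entropy
#'
#' Mean negative log-probability of the true next token over the non-pad
#' predicted positions: position t of the probability matrix predicts
#' target token t+1, for t up to trueLength - 1 (the end token included,
#' padding excluded). Content of pad rows is ignored.
#'
#' @param probs maxLen x vocabSize matrix of row-normalized probabilities
#'   (as returned by [fragnetDecode()])
#' @param targets encoded sequence from [encodeSequence()]
#' @return non-negative scalar
#' @export
reconstructionLoss <- function(probs, targets) {
  tl <- targets$trueLength
  idx <- seq_len(tl - 1L)
  ids <- targets$tokenIds[idx + 1L]
  if (any(ids < 0L) || any(ids >= ncol(probs)))
    stop("target token id out of range")
  p <- probs[cbind(idx, ids + 1L)]
  -mean(log(pmax(p, 1e-300)))
}

# gradient of reconstructionLoss at the logits (softmax + CE combined)
.recGrad <- function(probs, targets) {
  tl <- targets$trueLength
  idx <- seq_len(tl - 1L)
  ids <- targets$tokenIds[idx + 1L]
  d <- matrix(0, nrow(probs), ncol(probs))
  d[idx, ] <- probs[idx, , drop = FALSE]
  d[cbind(idx, ids + 1L)] <- d[cbind(idx, ids + 1L)] - 1
  d / length(idx)
}

#' Combined training objective
#'
#' \code{contrastiveWeight * contrastive + reconWeight * reconstruction}.
#' Setting \code{contrastiveWeight = 0} recovers the pure cross-entropy
#' baseline; \code{reconWeight = 0} gives pure contrastive training.
#'
#' @param contrastive NT-Xent value
#' @param reconstruction reconstruction cross-entropy value
#' @param config a [FragNetConfig-class] carrying the two weights
#' @return weighted sum
#' @export
totalLoss <- function(contrastive, reconstruction, config) {
  stopifnot(is.finite(contrastive), is.finite(reconstruction))
  config@contrastiveWeight * contrastive + config@reconWeight * reconstruction
}
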