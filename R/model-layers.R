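# Numerical primitives of the transformer: linear, layer norm, ReLU,
# multi-head attention and dropout, each as a forward returning (out, cache)
# and a matching backward. Gradients are derived by hand and guarded by
# finite-difference checks in the test suite.

# add a row vector b to every row of X (column-major broadcast)
.addRow <- function(X, b) X + rep(b, each = nrow(X))

#' Sinusoidal positional encoding
#'
#' Row \code{p + 1} holds the encoding of 0-based position \code{p}:
#' \eqn{PE[p, 2i] = \sin(p / 10000^{2i/d})} and
#' \eqn{PE[p, 2i+1] = \cos(p / 10000^{2i/d})} (0-based columns), the
#' standard transformer scheme that lets attention see token order.
#'
#' @param maxLen number of positions
#' @param dModel embedding width (even)
#' @return numeric matrix maxLen x dModel with entries in [-1, 1]
#' @examples
#' pe <- positionalEncoding(4L, 8L)
#' pe[1, ]   # position 0: sin terms 0, cos terms 1
#' @export
positionalEncoding <- function(maxLen, dModel) {
  stopifnot(maxLen >= 1L, dModel >= 2L, dModel %% 2L == 0L)
  pos <- 0:(maxLen - 1L)
  i <- 0:(dModel / 2L - 1L)
  ang <- outer(pos, 1 / 10000^(2 * i / dModel))
  pe <- matrix(0, maxLen, dModel)
  pe[, 2L * i + 1L] <- sin(ang)
  pe[, 2L * i + 2L] <- cos(ang)
  pe
}

.peCache <- new.env(parent = emptyenv())
.pe <- function(maxLen, dModel) {
  key <- paste0(maxLen, "x", dModel)
  if (is.null(.peCache[[key]]))
    .peCache[[key]] <- positionalEncoding(maxLen, dModel)
  .peCache[[key]]
}

.linFwd <- function(x, W, b) {
  list(out = .addRow(x %*% W, b), x = x)
}
.linBwd <- function(dy, cache, W) {
  list(dx = tcrossprod(dy, W), dW = crossprod(cache$x, dy),
       db = colSums(dy))
}

.reluFwd <- function(x) list(out = pmax(x, 0), keep = x > 0)
.reluBwd <- function(dy, cache) dy * cache$keep

.LN_EPS <- 1e-5
.lnFwd <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  va <- rowMeans(xc * xc)
  inv <- 1 / sqrt(va + .LN_EPS)
  xhat <- xc * inv
  list(out = .addRow(xhat * rep(g, each = nrow(x)), b),
       xhat = xhat, inv = inv)
}
.lnBwd <- function(dy, cache, g) {
  xhat <- cache$xhat
  dxhat <- dy * rep(g, each = nrow(dy))
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- cache$inv * (dxhat - m1 - xhat * m2)
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

.dropFwd <- function(x, p, training) {
  if (!training || p <= 0) return(list(out = x, mask = NULL))
  mask <- matrix(stats::runif(length(x)) >= p, nrow(x), ncol(x)) / (1 - p)
  list(out = x * mask, mask = mask)
}
.dropBwd <- function(dy, cache) {
  if (is.null(cache$mask)) dy else dy * cache$mask
}

# row-wise softmax over logits with -Inf style masking already applied
.softmaxRows <- function(s) {
  m <- s[cbind(seq_len(nrow(s)), max.col(s, ties.method = "first"))]
  e <- exp(s - m)
  e / rowSums(e)
}

# Multi-head attention. Xq: Lq x D queries source, Xkv: Lk x D key/value
# source, mask: Lq x Lk logical (TRUE = key visible to query).
.attnFwd <- function(Xq, Xkv, W, mask, nHeads) {
  D <- ncol(Xq); dk <- D %/% nHeads
  Q <- .addRow(Xq %*% W$Wq, W$bq)
  K <- .addRow(Xkv %*% W$Wk, W$bk)
  V <- .addRow(Xkv %*% W$Wv, W$bv)
  O <- matrix(0, nrow(Xq), D)
  A <- vector("list", nHeads)
  for (h in seq_len(nHeads)) {
    cols <- ((h - 1L) * dk + 1L):(h * dk)
    S <- tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) /
      sqrt(dk)
    S[!mask] <- -1e30
    A[[h]] <- .softmaxRows(S)
    O[, cols] <- A[[h]] %*% V[, cols, drop = FALSE]
  }
  Y <- .addRow(O %*% W$Wo, W$bo)
  list(out = Y, Q = Q, K = K, V = V, O = O, A = A, mask = mask,
       Xq = Xq, Xkv = Xkv)
}

.attnBwd <- function(dy, cache, W, nHeads) {
  D <- ncol(cache$Q); dk <- D %/% nHeads
  dO <- tcrossprod(dy, W$Wo)
  dWo <- crossprod(cache$O, dy)
  dbo <- colSums(dy)
  dQ <- matrix(0, nrow(cache$Q), D)
  dK <- matrix(0, nrow(cache$K), D)
  dV <- matrix(0, nrow(cache$V), D)
  for (h in seq_len(nHeads)) {
    cols <- ((h - 1L) * dk + 1L):(h * dk)
    A <- cache$A[[h]]
    Vh <- cache$V[, cols, drop = FALSE]
    dOh <- dO[, cols, drop = FALSE]
    dA <- tcrossprod(dOh, Vh)
    dV[, cols] <- crossprod(A, dOh)
    dS <- A * (dA - rowSums(A * dA))
    dS[!cache$mask] <- 0
    dQ[, cols] <- dS %*% cache$K[, cols, drop = FALSE] / sqrt(dk)
    dK[, cols] <- crossprod(dS, cache$Q[, cols, drop = FALSE]) / sqrt(dk)
  }
  list(dXq = tcrossprod(dQ, W$Wq),
       dXkv = tcrossprod(dK, W$Wk) + tcrossprod(dV, W$Wv),
       dWq = crossprod(cache$Xq, dQ), dbq = colSums(dQ),
       dWk = crossprod(cache$Xkv, dK), dbk = colSums(dK),
       dWv = crossprod(cache$Xkv, dV), dbv = colSums(dV),
       dWo = dWo, dbo = dbo)
}
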