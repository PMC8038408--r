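# Latent-space diagnostics: canonical-SMILES embedding, neighbor retrieval
# under cosine / Euclidean / Tanimoto, paired similarity tables for
# temperature cross-comparison, dimension-population sparsity traces,
# per-dimension histograms with representative molecules, and seeded
# t-SNE/UMAP 2-D maps.

#' Embed a corpus into the latent space
#'
#' Projects the canonical SMILES of every record through the trained
#' encoder and projection head in evaluation mode (dropout off), the only
#' place canonical strings are consumed. Deterministic: repeated calls
#' give identical matrices.
#'
#' @param records molecule records
#' @param model a trained [FragNetModel-class]
#' @return a [LatentMatrix-class] (n x dModel, entries >= 0)
#' @export
embedCorpus <- function(records, model) {
  cfg <- model@config
  Z <- matrix(0, nrow(records), cfg@dModel)
  for (i in seq_len(nrow(records))) {
    h <- fragnetEncode(model, records$smiles[i], oov = "error")
    Z[i, ] <- fragnetProject(model, h)
  }
  latentMatrix(records$id, Z, cfg@temperature)
}

#' Path-based fingerprint on-bit sets
#'
#' Open Babel FP2 fingerprints: linear substructure paths hashed into 1024
#' bits, the same fingerprint family as RDKit's path-based RDKFingerprint.
#'
#' @param smiles character vector of SMILES
#' @return list of sorted integer vectors of on-bit indices (1-based)
#' @export
fingerprintBits <- function(smiles) {
  mols <- ChemmineOB::forEachMol("SMILES",
                                 paste(smiles, collapse = "\n"), identity)
  fp <- ChemmineOB::fingerprint_OB(mols, "FP2")
  if (nrow(fp) != length(smiles))
    stop("fingerprinting failed for at least one SMILES")
  lapply(seq_len(nrow(fp)), function(i) which(fp[i, ] != 0))
}

#' Tanimoto similarity of two molecules
#'
#' \eqn{|A \cap B| / |A \cup B|} over the on-bit sets of the two FP2
#' fingerprints. Two molecules too small to set any bit count as identical
#' (similarity 1).
#'
#' @param smilesA,smilesB SMILES strings
#' @return similarity in [0, 1]
#' @export
tanimotoSimilarity <- function(smilesA, smilesB) {
  bits <- fingerprintBits(c(smilesA, smilesB))
  u <- length(union(bits[[1]], bits[[2]]))
  if (u == 0) return(1)
  length(intersect(bits[[1]], bits[[2]])) / u
}

# all three similarity columns of a query against a latent matrix
.allMetrics <- function(qz, qsmiles, latents, corpus = NULL) {
  V <- latents@vectors
  nq <- sqrt(sum(qz * qz))
  nr <- sqrt(rowSums(V * V))
  dots <- as.numeric(V %*% qz)
  cosv <- ifelse(nq > 0 & nr > 0, dots / (nq * nr), 0)
  eucl <- sqrt(pmax(rowSums(V * V) - 2 * dots + sum(qz * qz), 0))
  tani <- rep(NA_real_, nrow(V))
  if (!is.null(corpus) && !is.null(qsmiles)) {
    sm <- corpus$smiles[match(latents@ids, corpus$id)]
    if (anyNA(sm)) stop("latent ids missing from corpus")
    bits <- fingerprintBits(c(qsmiles, sm))
    qb <- bits[[1]]
    tani <- vapply(seq_along(sm), function(i) {
      u <- length(union(qb, bits[[i + 1L]]))
      if (u == 0) 1 else length(intersect(qb, bits[[i + 1L]])) / u
    }, numeric(1))
  }
  data.frame(neighbor_id = latents@ids, cosine = cosv, euclidean = eucl,
             tanimoto = tani, stringsAsFactors = FALSE)
}

#' Retrieve the nearest neighbors of a molecule
#'
#' Ranks the corpus by the chosen metric (cosine and Tanimoto descending,
#' Euclidean ascending; ties broken lexicographically by id) and reports
#' all three metric values for each of the top k neighbors. A query
#' present in the corpus ranks itself first.
#'
#' @param query a one-row molecule record (id + smiles); if its id is
#'   absent from \code{latents}, a \code{model} is required to embed it
#' @param latents a [LatentMatrix-class]
#' @param corpus the molecule records behind \code{latents} (needed for
#'   Tanimoto values)
#' @param metric ranking metric
#' @param k number of neighbors (k <= n)
#' @param model optional [FragNetModel-class] for out-of-corpus queries
#' @return data.frame: query_id, neighbor_id, cosine, euclidean, tanimoto
#' @export
neighborQuery <- function(query, latents, corpus,
                          metric = c("cosine", "euclidean", "tanimoto"),
                          k = 10L, model = NULL) {
  metric <- match.arg(metric)
  n <- length(latents@ids)
  if (k > n) stop("k (", k, ") exceeds corpus size (", n, ")")
  qid <- query$id
  if (qid %in% latents@ids) {
    qz <- latents@vectors[match(qid, latents@ids), ]
  } else if (!is.null(model)) {
    qz <- fragnetProject(model, fragnetEncode(model, query$smiles,
                                              oov = "error"))
  } else {
    stop("query id '", qid, "' not in latents and no model supplied")
  }
  tab <- .allMetrics(qz, query$smiles, latents, corpus)
  ord <- switch(metric,
    cosine = order(-tab$cosine, tab$neighbor_id, method = "radix"),
    tanimoto = order(-tab$tanimoto, tab$neighbor_id, method = "radix"),
    euclidean = order(tab$euclidean, tab$neighbor_id, method = "radix"))
  out <- tab[ord[seq_len(k)], , drop = FALSE]
  cbind(data.frame(query_id = qid, stringsAsFactors = FALSE), out,
        row.names = NULL)
}

#' Paired similarity table for scatter plots
#'
#' For a fixed query molecule, pairs a similarity value per corpus
#' molecule on the x axis with one on the y axis: either the same metric
#' under two models (e.g. cosine at two temperatures) or two different
#' metrics under one model (cosine vs Euclidean, cosine vs Tanimoto).
#' The query itself is excluded.
#'
#' @param query one-row molecule record present in the latent matrices
#' @param latentsX,latentsY [LatentMatrix-class] objects over the same ids
#'   (\code{latentsY} defaults to \code{latentsX})
#' @param metricX,metricY \code{"cosine"}, \code{"euclidean"} or
#'   \code{"tanimoto"}
#' @param corpus molecule records (required when a metric is tanimoto)
#' @return data.frame: id, x, y; attributes \code{xlab}/\code{ylab} name
#'   the axes including the source temperature
#' @export
similarityScatter <- function(query, latentsX, latentsY = latentsX,
                              metricX = "cosine", metricY = "cosine",
                              corpus = NULL) {
  if (!identical(latentsX@ids, latentsY@ids))
    stop("latent matrices cover different ids")
  pick <- function(latents, metric) {
    i <- match(query$id, latents@ids)
    if (is.na(i)) stop("query id '", query$id, "' not in latents")
    tab <- .allMetrics(latents@vectors[i, ], query$smiles, latents,
                       if (metric == "tanimoto") corpus else NULL)
    tab[[metric]]
  }
  x <- pick(latentsX, metricX)
  y <- pick(latentsY, metricY)
  keep <- latentsX@ids != query$id
  structure(
    data.frame(id = latentsX@ids[keep], x = x[keep], y = y[keep],
               stringsAsFactors = FALSE),
    xlab = sprintf("%s (tau=%s)", metricX,
                   format(latentsX@sourceTemperature)),
    ylab = sprintf("%s (tau=%s)", metricY,
                   format(latentsY@sourceTemperature)))
}

#' Dimension-population sparsity traces
#'
#' How many latent dimensions the corpus actually uses. An entry is
#' "populated" when its magnitude exceeds \code{epsilon} (default 0,
#' exact: the ReLU head produces exact zeros). Three traces summarise the
#' per-molecule populated-dimension counts: the number of dimensions
#' nonzero for every molecule, the mean count, and the maximum count.
#'
#' @param latents a [LatentMatrix-class] (or bare matrix)
#' @param epsilon non-negative threshold
#' @return list of class \code{dimensionPopulation} with
#'   \code{alwaysNonzero}, \code{meanNonzero}, \code{maxNonzero},
#'   \code{dimensionality}; invariant always <= mean <= max <= D
#' @export
dimensionPopulation <- function(latents, epsilon = 0) {
  V <- if (is(latents, "LatentMatrix")) latents@vectors else as.matrix(latents)
  nz <- abs(V) > epsilon
  perRow <- rowSums(nz)
  structure(list(
    alwaysNonzero = sum(colSums(nz) == nrow(nz)),
    meanNonzero = mean(perRow),
    maxNonzero = max(perRow),
    dimensionality = ncol(V)), class = "dimensionPopulation")
}

#' @export
print.dimensionPopulation <- function(x, ...) {
  cat(sprintf(paste0("dimension population (D = %d): always nonzero %d, ",
                     "mean %.2f, max %d\n"),
              x$dimensionality, x$alwaysNonzero, x$meanNonzero,
              x$maxNonzero))
  invisible(x)
}

#' Histogram of one latent dimension with representative molecules
#'
#' Equal-width bins over the observed range of the dimension; for each
#' requested bin, the ids of the molecules whose value lies closest to the
#' bin center are reported (deterministic, ties by id).
#'
#' @param latents a [LatentMatrix-class]
#' @param dim dimension, 1-based, 1 <= dim <= dModel
#' @param nBins number of bins
#' @param nReps representatives per bin
#' @return list with \code{breaks}, \code{counts} (summing to n),
#'   \code{mids} and \code{representatives} (list of id vectors per bin)
#' @export
dimensionHistogram <- function(latents, dim, nBins = 20L, nReps = 3L) {
  V <- latents@vectors
  if (dim < 1L || dim > ncol(V))
    stop("dim must be in 1..", ncol(V))
  x <- V[, dim]
  r <- range(x)
  if (r[1] == r[2]) r <- r + c(-0.5, 0.5)          # constant column
  breaks <- seq(r[1], r[2], length.out = nBins + 1L)
  bin <- pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE), 1L),
              nBins)
  counts <- tabulate(bin, nbins = nBins)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  reps <- lapply(seq_len(nBins), function(b) {
    ids <- latents@ids[bin == b]
    if (!length(ids)) return(character(0))
    d <- abs(x[bin == b] - mids[b])
    ids[order(d, ids, method = "radix")][seq_len(min(nReps, length(ids)))]
  })
  list(breaks = breaks, counts = counts, mids = mids,
       representatives = reps)
}

#' 2-D map of the latent space
#'
#' Delegates to the established t-SNE (Rtsne) or UMAP (uwot)
#' implementations under a fixed seed and optionally writes the
#' coordinates as CSV and a class-coloured scatter as PNG.
#'
#' @param latents a [LatentMatrix-class] (n >= 5)
#' @param method \code{"tsne"} or \code{"umap"}
#' @param seed RNG seed (same seed, same coordinates)
#' @param labels optional class labels per molecule (colors)
#' @param perplexity t-SNE perplexity; default adapts to small n
#' @param nNeighbors UMAP neighbourhood size
#' @param outCsv,outPng optional output paths
#' @return n x 2 coordinate matrix with ids as rownames
#' @export
map2d <- function(latents, method = c("tsne", "umap"), seed = 1L,
                  labels = NULL, perplexity = NULL, nNeighbors = 15L,
                  outCsv = NULL, outPng = NULL) {
  method <- match.arg(method)
  V <- latents@vectors
  n <- nrow(V)
  if (n < 5L) stop("need at least 5 molecules for a 2-D map")
  if (method == "tsne") {
    if (!requireNamespace("Rtsne", quietly = TRUE))
      stop("package Rtsne is required for method = 'tsne'")
    if (is.null(perplexity))
      perplexity <- max(2, min(30, floor((n - 1) / 3)))
    co <- .withSeed(seed,
      Rtsne::Rtsne(V, perplexity = perplexity, check_duplicates = FALSE,
                   pca = FALSE, theta = 0.0, max_iter = 500)$Y)
  } else {
    if (!requireNamespace("uwot", quietly = TRUE))
      stop("package uwot is required for method = 'umap'")
    co <- .withSeed(seed,
      uwot::umap(V, n_neighbors = min(nNeighbors, n - 1L),
                 n_threads = 1, n_sgd_threads = 1))
  }
  rownames(co) <- latents@ids
  colnames(co) <- c("x", "y")
  if (!is.null(outCsv)) {
    df <- data.frame(id = latents@ids, x = co[, 1], y = co[, 2])
    if (!is.null(labels)) df$label <- labels
    utils::write.csv(df, outCsv, row.names = FALSE)
  }
  if (!is.null(outPng)) {
    grDevices::png(outPng, width = 800, height = 700)
    on.exit(grDevices::dev.off())
    col <- if (is.null(labels)) "steelblue" else
      as.integer(factor(labels)) + 1L
    graphics::plot(co, col = col, pch = 19,
                   xlab = paste(method, "1"), ylab = paste(method, "2"),
                   main = sprintf("%s map of %d molecules", method, n))
    if (!is.null(labels))
      graphics::legend("topright", legend = levels(factor(labels)),
                       col = seq_along(levels(factor(labels))) + 1L,
                       pch = 19)
  }
  co
}

#' Mean within-group vs between-group cosine similarity
#'
#' Summarises how well the latent space clusters a grouping (scaffold
#' families, compound classes): the mean pairwise cosine similarity of
#' molecules sharing a group versus that of molecules in different groups.
#'
#' @param latents a [LatentMatrix-class]
#' @param groups group label per molecule (same order as the latent ids)
#' @return list with \code{within}, \code{between} and \code{gap}
#'   (within - between)
#' @export
familySimilarityGap <- function(latents, groups) {
  V <- latents@vectors
  stopifnot(length(groups) == nrow(V))
  un <- .unitRows(V)
  C <- tcrossprod(un$U)
  same <- outer(groups, groups, "==")
  ut <- upper.tri(C)
  within <- mean(C[ut & same])
  between <- mean(C[ut & !same])
  list(within = within, between = between, gap = within - between)
}
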