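## TransE scoring, subgraph embedding-matrix construction, and the
## size-invariant Conv -> global-average-pool -> projection aggregator
## that turns a variable-row matrix of entity/relation embeddings into a
## fixed-width knowledge-graph vector.

#' TransE triple score
#'
#' Squared Euclidean norm of h + r - t; 0 means an exact translation
#' (a maximally plausible triple).
#'
#' @param h,r,t Numeric vectors of equal dimension.
#' @return Nonnegative scalar.
#' @examples
#' transeScore(c(1, 0), c(0, 1), c(1, 1))  # 0
#' @export
transeScore <- function(h, r, t) {
  if (length(h) != length(r) || length(h) != length(t))
    stop("h, r, t must share one dimension")
  sum((h + r - t)^2)
}

#' Train toy TransE embeddings on a small triple set
#'
#' Margin-based ranking loss over positive vs head/tail-corrupted triples,
#' optimized by SGD with per-step renormalization of entity vectors.
#' This exists to produce realistic synthetic embedding stores for tests
#' and demonstrations, not to train at knowledge-base scale.
#'
#' @param kg A \linkS4class{HeteroKG} (its triples are the training set).
#' @param dim Embedding dimension.
#' @param margin Ranking margin (default 1).
#' @param epochs Training epochs (0 leaves the initialization untouched).
#' @param lr SGD learning rate.
#' @param rngSeed Integer seed (initialization and corruption sampling).
#' @return An \linkS4class{EmbeddingStore} covering all entities and
#'   relation types.
#' @export
trainToyTransE <- function(kg, dim = 16L, margin = 1, epochs = 100L,
                           lr = 0.01, rngSeed = 1L) {
  tr <- kg@triples
  if (nrow(tr) == 0L) stop("empty triple set")
  ents <- sort(unique(c(tr$head, tr$tail)))
  rels <- sort(unique(tr$relation))
  set.seed(rngSeed)
  emb <- matrix(stats::rnorm(length(c(ents, rels)) * dim, sd = 1 / sqrt(dim)),
                ncol = dim)
  rownames(emb) <- c(ents, rels)
  hI <- match(tr$head, rownames(emb))
  rI <- match(tr$relation, rownames(emb))
  tI <- match(tr$tail, rownames(emb))
  n <- nrow(tr)
  for (ep in seq_len(epochs)) {
    ## corrupt head or tail with a uniformly random entity
    corrHead <- stats::runif(n) < 0.5
    corr <- match(ents[sample.int(length(ents), n, replace = TRUE)],
                  rownames(emb))
    chI <- ifelse(corrHead, corr, hI)
    ctI <- ifelse(corrHead, tI, corr)
    dPos <- emb[hI, , drop = FALSE] + emb[rI, , drop = FALSE] -
      emb[tI, , drop = FALSE]
    dNeg <- emb[chI, , drop = FALSE] + emb[rI, , drop = FALSE] -
      emb[ctI, , drop = FALSE]
    viol <- margin + rowSums(dPos^2) - rowSums(dNeg^2) > 0
    if (!any(viol)) next
    for (i in which(viol)) {
      gp <- 2 * dPos[i, ]
      gn <- 2 * dNeg[i, ]
      emb[hI[i], ] <- emb[hI[i], ] - lr * gp
      emb[rI[i], ] <- emb[rI[i], ] - lr * (gp - gn)
      emb[tI[i], ] <- emb[tI[i], ] + lr * gp
      emb[chI[i], ] <- emb[chI[i], ] + lr * gn
      emb[ctI[i], ] <- emb[ctI[i], ] - lr * gn
    }
    eIdx <- match(ents, rownames(emb))
    nrm <- sqrt(rowSums(emb[eIdx, , drop = FALSE]^2))
    emb[eIdx, ] <- emb[eIdx, , drop = FALSE] / pmax(nrm, 1)
  }
  methods::new("EmbeddingStore", vectors = emb)
}

#' Mean TransE scores of true vs corrupted triples
#'
#' Diagnostic used by tests and the toy-trainer sanity check.
#' @param kg A \linkS4class{HeteroKG}.
#' @param store An \linkS4class{EmbeddingStore}.
#' @param rngSeed Seed for the corruption draw.
#' @return Named numeric \code{c(positive=, corrupted=)}.
#' @export
transeSeparation <- function(kg, store, rngSeed = 1L) {
  tr <- kg@triples
  ents <- sort(unique(c(tr$head, tr$tail)))
  H <- embeddingLookup(store, tr$head)
  R <- embeddingLookup(store, tr$relation)
  Tl <- embeddingLookup(store, tr$tail)
  set.seed(rngSeed)
  corrHead <- stats::runif(nrow(tr)) < 0.5
  corr <- embeddingLookup(store,
                          ents[sample.int(length(ents), nrow(tr),
                                          replace = TRUE)])
  Hc <- H; Tc <- Tl
  Hc[corrHead, ] <- corr[corrHead, , drop = FALSE]
  Tc[!corrHead, ] <- corr[!corrHead, , drop = FALSE]
  c(positive = mean(rowSums((H + R - Tl)^2)),
    corrupted = mean(rowSums((Hc + R - Tc)^2)))
}

#' Stack a drug subgraph's embeddings into its matrix M_d
#'
#' Rows are the subgraph's entities in lexicographic order followed by its
#' distinct relation types in lexicographic order (S = |E_d| + |R_d|), each
#' row the stored embedding of its identifier. No aggregation is applied
#' before projection.
#'
#' @param subgraph A \linkS4class{DrugSubgraph}.
#' @param store An \linkS4class{EmbeddingStore}; a missing identifier is an
#'   error naming it, never a silent zero.
#' @return List with \code{M} (S x dim matrix) and \code{rowIndex}
#'   (data.frame kind/identifier, in row order).
#' @export
buildSubgraphMatrix <- function(subgraph, store) {
  if (subgraph@unreachable)
    stop("cannot build a matrix for a pathway-unreachable drug: ",
         subgraph@drug)
  ents <- sort(subgraph@entities)
  rels <- sort(subgraph@relations)
  M <- embeddingLookup(store, c(ents, rels))
  list(M = M,
       rowIndex = data.frame(
         kind = c(rep("entity", length(ents)), rep("relation", length(rels))),
         identifier = c(ents, rels), stringsAsFactors = FALSE))
}

## valid cross-correlation output length for size n, kernel k, stride s,
## zero padding p (extra bottom padding keeps 1 output cell for tiny n)
.convOutLen <- function(n, k = 5L, s = 3L, p = 1L) {
  max(1L, (n + 2L * p - k) %/% s + 1L)
}

#' im2col patch matrix for a single-channel 2-D convolution
#'
#' Unfolds a zero-padded matrix into one row per output cell and one
#' column per kernel element, so the convolution becomes a matrix product.
#' Inputs smaller than the kernel after padding gain extra zero rows or
#' columns at the bottom/right so at least one output cell exists.
#' @keywords internal
im2col <- function(M, kernel = 5L, stride = 3L, pad = 1L) {
  n <- nrow(M); m <- ncol(M)
  hOut <- .convOutLen(n, kernel, stride, pad)
  wOut <- .convOutLen(m, kernel, stride, pad)
  padded <- matrix(0, max(n + 2L * pad, (hOut - 1L) * stride + kernel),
                   max(m + 2L * pad, (wOut - 1L) * stride + kernel))
  padded[pad + seq_len(n), pad + seq_len(m)] <- M
  cols <- matrix(0, hOut * wOut, kernel * kernel)
  cell <- 0L
  for (i in seq_len(hOut)) {
    ri <- (i - 1L) * stride
    for (j in seq_len(wOut)) {
      cj <- (j - 1L) * stride
      cell <- cell + 1L
      cols[cell, ] <- as.numeric(padded[ri + seq_len(kernel),
                                        cj + seq_len(kernel)])
    }
  }
  structure(cols, hOut = hOut, wOut = wOut)
}

#' Initialize the Conv -> GAP -> FC aggregator parameters
#'
#' @param dKg Output width of the knowledge-graph vector.
#' @param channels Convolution output channels.
#' @param kernel,stride,pad Convolution geometry.
#' @return Parameter list (autodiff parameter nodes).
#' @export
kgAggregatorInit <- function(dKg = 20L, channels = 128L, kernel = 5L,
                             stride = 3L, pad = 1L) {
  k2 <- kernel * kernel
  list(kernel = kernel, stride = stride, pad = pad, channels = channels,
       Wc = adParam(matrix(stats::rnorm(k2 * channels, sd = sqrt(2 / k2)),
                           k2, channels)),
       bc = adParam(matrix(0, 1L, channels)),
       Wf = adParam(matrix(stats::rnorm(channels * dKg,
                                        sd = sqrt(1 / channels)),
                           channels, dKg)),
       bf = adParam(matrix(0, 1L, dKg)))
}

#' Size-invariant subgraph aggregation: Conv2D -> GAP -> FC
#'
#' Treats M_d as a 1-channel S x dim grid, applies a 2-D convolution
#' (kernel 5x5, stride 3x3, zero padding 1, C output channels) followed by
#' a LeakyReLU, global average pooling over the spatial grid, and an affine
#' projection to the knowledge-graph vector. The output width never
#' depends on S.
#'
#' @param M S x dim numeric matrix (S >= 1), or a precomputed
#'   \code{\link{im2col}} patch matrix.
#' @param params Aggregator parameters from \code{\link{kgAggregatorInit}}.
#' @return Autodiff node with a 1 x dKg value (read \code{$value} outside
#'   training).
#' @export
convGapProject <- function(M, params) {
  cols <- if (!is.null(attr(M, "hOut"))) M
          else {
            if (nrow(M) < 1L) stop("subgraph matrix must have S >= 1 rows")
            im2col(M, params$kernel, params$stride, params$pad)
          }
  conv <- adLeakyRelu(adAddBias(adMatmul(adConst(cols), params$Wc),
                                params$bc))
  pool <- adMatmul(adConst(matrix(1 / nrow(cols), 1L, nrow(cols))), conv)
  adAddBias(adMatmul(pool, params$Wf), params$bf)
}

#' Spatial grid dimensions after the aggregator's convolution
#' @param S Subgraph row count.
#' @param dim Embedding dimension.
#' @param kernel,stride,pad Convolution geometry.
#' @return Integer vector (rows, cols) of the output grid.
#' @export
convGridDim <- function(S, dim, kernel = 5L, stride = 3L, pad = 1L) {
  c(.convOutLen(S, kernel, stride, pad), .convOutLen(dim, kernel, stride, pad))
}
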