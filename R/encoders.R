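## Molecular encoder branches: the Transformer over SMILES token sequences
## (sequence semantics; <CLS> readout; padding masked out of attention) and
## the K-head graph attention network over the SMILES-derived molecular
## graph (bond-constrained message passing; masked atom readout with a
## residual MLP). Both are written on the package's autodiff core so they
## train jointly with the fusion classifier.

.initW <- function(nin, nout) {
  adParam(matrix(stats::rnorm(nin * nout, sd = sqrt(1 / nin)), nin, nout))
}

#' Initialize Transformer-branch parameters
#'
#' A learned token embedding (width dEmb), a linear projection to dModel,
#' and nLayers post-norm encoder layers with nHead self-attention heads
#' and feed-forward width dFf. No positional-encoding module is added in
#' this branch: position-aware signals enter the model only through the
#' graph branch's node features.
#'
#' @param vocabSize Vocabulary size (token IDs 0 .. vocabSize-1).
#' @param dEmb,dModel,nLayers,nHead,dFf Dimensions; dModel must be
#'   divisible by nHead.
#' @return Parameter list.
#' @export
transformerInit <- function(vocabSize, dEmb = 128L, dModel = 128L,
                            nLayers = 2L, nHead = 4L, dFf = 256L) {
  if (dModel %% nHead != 0L) stop("dModel must be divisible by nHead")
  layers <- lapply(seq_len(nLayers), function(i) list(
    Wq = .initW(dModel, dModel), Wk = .initW(dModel, dModel),
    Wv = .initW(dModel, dModel), Wo = .initW(dModel, dModel),
    bo = adParam(matrix(0, 1L, dModel)),
    ln1g = adParam(matrix(1, 1L, dModel)),
    ln1b = adParam(matrix(0, 1L, dModel)),
    W1 = .initW(dModel, dFf), b1 = adParam(matrix(0, 1L, dFf)),
    W2 = .initW(dFf, dModel), b2 = adParam(matrix(0, 1L, dModel)),
    ln2g = adParam(matrix(1, 1L, dModel)),
    ln2b = adParam(matrix(0, 1L, dModel))))
  list(dEmb = dEmb, dModel = dModel, nHead = nHead,
       tokEmb = adParam(matrix(stats::rnorm(vocabSize * dEmb,
                                            sd = sqrt(1 / dEmb)),
                               vocabSize, dEmb)),
       Wproj = .initW(dEmb, dModel),
       bproj = adParam(matrix(0, 1L, dModel)),
       layers = layers)
}

## one-hot L x V selection matrix for 0-based token IDs
.onehot <- function(ids, vocabSize) {
  H <- matrix(0, length(ids), vocabSize)
  H[cbind(seq_along(ids), ids + 1L)] <- 1
  H
}

#' Encode a token sequence with the Transformer branch
#'
#' Embeds tokens, projects to dModel, applies the encoder stack with a
#' padding mask (attention never reads \code{<PAD>} positions, so the
#' output is exactly invariant to the padded tail length), and returns the
#' \code{<CLS>} row as the sequence-level representation.
#'
#' @param seq A \linkS4class{TokenSequence}. Its length must equal the L
#'   the model was configured for.
#' @param params From \code{\link{transformerInit}}.
#' @param L Configured sequence length.
#' @param tokEmb Optional embedding node to use instead of
#'   \code{params$tokEmb} (the model shares one token embedding between
#'   branches).
#' @return Autodiff node with a 1 x dModel value (z_trans).
#' @export
encodeSequence <- function(seq, params, L = length(seq@ids),
                           tokEmb = NULL) {
  ids <- seq@ids
  if (length(ids) != L)
    stop("sequence length ", length(ids), " does not match configured L = ",
         L)
  emb <- if (is.null(tokEmb)) params$tokEmb else tokEmb
  oh <- .onehot(ids, nrow(emb$value))
  X <- adAddBias(adMatmul(adMatmul(adConst(oh), emb), params$Wproj),
                 params$bproj)
  real <- which(seq@mask)
  attMask <- matrix(0, L, L)
  attMask[, real] <- 1  # every query may read every non-PAD key
  nHead <- params$nHead
  dModel <- ncol(params$Wproj$value)
  dk <- dModel %/% nHead
  for (layer in params$layers) {
    Q <- adMatmul(X, layer$Wq)
    K <- adMatmul(X, layer$Wk)
    V <- adMatmul(X, layer$Wv)
    heads <- vector("list", nHead)
    for (h in seq_len(nHead)) {
      sel <- matrix(0, dModel, dk)
      sel[cbind((h - 1L) * dk + seq_len(dk), seq_len(dk))] <- 1
      S <- adConst(sel)
      Qh <- adMatmul(Q, S); Kh <- adMatmul(K, S); Vh <- adMatmul(V, S)
      att <- adMaskedSoftmaxRows(
        adScale(adMatmul(Qh, adTranspose(Kh)), 1 / sqrt(dk)), attMask)
      heads[[h]] <- adMatmul(att, Vh)
    }
    A <- adAddBias(adMatmul(adConcatCols(heads), layer$Wo), layer$bo)
    X <- adLayerNormRows(adAdd(X, A), layer$ln1g, layer$ln1b)
    FF <- adAddBias(adMatmul(
      adRelu(adAddBias(adMatmul(X, layer$W1), layer$b1)), layer$W2),
      layer$b2)
    X <- adLayerNormRows(adAdd(X, FF), layer$ln2g, layer$ln2b)
  }
  cls <- matrix(0, 1L, L); cls[1L, 1L] <- 1
  adMatmul(adConst(cls), X)
}

#' Initialize GAT-branch parameters
#'
#' K attention heads of width dPrime each (concatenated output width
#' K * dPrime) plus a residual MLP applied after readout.
#'
#' @param dIn Node-feature width (the token-embedding width).
#' @param kHeads,dPrime Head count and per-head width.
#' @return Parameter list.
#' @export
gatInit <- function(dIn, kHeads = 4L, dPrime = 16L) {
  heads <- lapply(seq_len(kHeads), function(k) list(
    W = .initW(dIn, dPrime),
    a1 = .initW(dPrime, 1L),
    a2 = .initW(dPrime, 1L)))
  w <- kHeads * dPrime
  list(kHeads = kHeads, dPrime = dPrime, heads = heads,
       mlpW1 = .initW(w, w), mlpB1 = adParam(matrix(0, 1L, w)),
       mlpW2 = .initW(w, w), mlpB2 = adParam(matrix(0, 1L, w)))
}

#' Single-head GAT attention matrix
#'
#' Softmax over each node's neighborhood of
#' LeakyReLU(a^T [W h_i || W h_j]), defined only on the edges of A
#' (self-loops included when present in A); non-edges get exactly zero and
#' every row with at least one neighbor sums to 1.
#'
#' @param H L x d node-feature matrix (plain numeric).
#' @param A L x L adjacency (weights define the edge set).
#' @param head One element of \code{gatInit()$heads}.
#' @param negativeSlope LeakyReLU slope for the logits (default 0.2).
#' @return List with node \code{alpha} (autodiff) and the edge mask used.
#' @export
gatAttention <- function(H, A, head, negativeSlope = 0.2) {
  L <- nrow(A)
  mask <- (A != 0) * 1
  Hn <- if (is.environment(H)) H else adConst(H)
  Wh <- adMatmul(Hn, head$W)
  f1 <- adMatmul(Wh, head$a1)
  f2 <- adMatmul(Wh, head$a2)
  logits <- adAdd(adMatmul(f1, adConst(matrix(1, 1L, L))),
                  adMatmul(adConst(matrix(1, L, 1L)), adTranspose(f2)))
  alpha <- adMaskedSoftmaxRows(adLeakyRelu(logits, negativeSlope), mask)
  list(alpha = alpha, Wh = Wh, mask = mask)
}

#' One K-head GAT layer
#'
#' Per head: attention-weighted aggregation of transformed neighbor
#' features (optionally scaled by the bond-multiplicity weights of A),
#' then an ELU nonlinearity; heads are concatenated to width K * dPrime.
#'
#' @param H L x d node features (numeric matrix or autodiff node).
#' @param A L x L adjacency.
#' @param params From \code{\link{gatInit}}.
#' @param useEdgeWeights Scale messages by A's weights (default TRUE);
#'   when FALSE the weights only define the edge set.
#' @return Autodiff node, L x (K * dPrime).
#' @export
gatLayer <- function(H, A, params, useEdgeWeights = TRUE) {
  outs <- lapply(params$heads, function(head) {
    at <- gatAttention(H, A, head)
    alpha <- at$alpha
    if (useEdgeWeights) alpha <- adHadamardConst(alpha, A)
    adElu(adMatmul(alpha, at$Wh))
  })
  adConcatCols(outs)
}

#' Masked readout with residual MLP
#'
#' Pools node outputs over atom positions only (mean or max), then applies
#' a one-hidden-layer MLP with a skip connection from the pooled vector to
#' the output (z_gat, width K * dPrime).
#'
#' @param nodeOut Autodiff node, L x w.
#' @param atomMask Logical length-L atom indicator (>= 1 atom required).
#' @param params From \code{\link{gatInit}}.
#' @param mode \code{"mean"} or \code{"max"}.
#' @return Autodiff node, 1 x w.
#' @export
gatReadout <- function(nodeOut, atomMask, params, mode = c("mean", "max")) {
  mode <- match.arg(mode)
  atoms <- which(atomMask)
  if (length(atoms) == 0L) stop("readout requires at least one atom node")
  pooled <- if (mode == "mean") {
    sel <- matrix(0, 1L, length(atomMask))
    sel[1L, atoms] <- 1 / length(atoms)
    adMatmul(adConst(sel), nodeOut)
  } else {
    adColMaxRows(nodeOut, atoms)
  }
  h <- adLeakyRelu(adAddBias(adMatmul(pooled, params$mlpW1), params$mlpB1))
  adAdd(pooled, adAddBias(adMatmul(h, params$mlpW2), params$mlpB2))
}

#' Encode a molecular graph with the GAT branch
#'
#' Builds position-aware node features H~ = E + P on atom rows (zero
#' elsewhere), applies the GAT layer and the masked readout.
#'
#' @param seq A \linkS4class{TokenSequence}.
#' @param graph The matching \linkS4class{MolecularGraph}.
#' @param params From \code{\link{gatInit}}.
#' @param tokEmb Token-embedding parameter node (V x dEmb).
#' @param P Positional-encoding matrix (L x dEmb), or NULL to omit the
#'   positional signal (ablation mode).
#' @param readout \code{"mean"} or \code{"max"}.
#' @param useEdgeWeights See \code{\link{gatLayer}}.
#' @return Autodiff node, 1 x (K * dPrime) (z_gat).
#' @export
encodeGraph <- function(seq, graph, params, tokEmb, P = NULL,
                        readout = "mean", useEdgeWeights = TRUE) {
  A <- graph@adjacency
  L <- nrow(A)
  am <- graph@atomMask
  oh <- .onehot(seq@ids, nrow(tokEmb$value))
  oh[!am, ] <- 0  # zero embeddings at non-atom rows
  E <- adMatmul(adConst(oh), tokEmb)
  H <- if (is.null(P)) E else {
    Pm <- P
    Pm[!am, ] <- 0
    adAdd(E, adConst(Pm))
  }
  out <- gatLayer(H, A, params, useEdgeWeights = useEdgeWeights)
  gatReadout(out, am, params, mode = readout)
}
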