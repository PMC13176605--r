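## The fused DDI model: per-drug representations from the three branches,
## pair-feature concatenation, and the fully connected classifier head
## (batch normalization + LeakyReLU + dropout).

.ablationVariants <- c("transformer", "gat", "transformer+gat", "kg-rw",
                       "kg-rw+sp", "transformer+kg-rw",
                       "transformer+kg-rw+sp", "full")

#' Blocks of the fusion vector used by an ablation variant
#' @param variant One of the supported run modes.
#' @return List with logical \code{trans}, \code{gat}, \code{kg} and
#'   \code{anchored} (whether KG subgraphs use the pathway-anchored
#'   shortest-path extraction or the raw random-walk neighborhood).
#' @export
ablationBlocks <- function(variant = "full") {
  if (!variant %in% .ablationVariants)
    stop("unknown ablation variant: ", variant, " (supported: ",
         paste(.ablationVariants, collapse = ", "), ")")
  list(trans = grepl("transformer|full", variant),
       gat = variant %in% c("gat", "transformer+gat", "full"),
       kg = grepl("kg|full", variant),
       anchored = !grepl("kg-rw$", variant))
}

#' Width of the fused pair feature
#'
#' D = 2 (dModel + K dPrime + dKg), restricted to the blocks active in the
#' configured ablation variant.
#' @param config A \code{\link{runConfig}}.
#' @return Integer D.
#' @export
pairFeatureDim <- function(config) {
  b <- ablationBlocks(config$ablation)
  2L * (b$trans * config$dModel + b$gat * config$kHeads * config$dPrime +
        b$kg * config$dKg)
}

#' Fuse two drugs' representations into one pair feature
#'
#' Concatenation in the fixed order
#' [z_trans_a, z_gat_a, z_kg_a, z_trans_b, z_gat_b, z_kg_b]; blocks absent
#' from the active ablation variant are skipped on both sides. Swapping
#' the drugs permutes the vector, so pair order matters.
#'
#' @param repsA,repsB Lists with numeric vectors \code{trans}, \code{gat},
#'   \code{kg} (entries may be NULL when the block is inactive).
#' @param blocks From \code{\link{ablationBlocks}}.
#' @return Numeric pair-feature vector.
#' @export
fusePair <- function(repsA, repsB, blocks = ablationBlocks("full")) {
  pick <- function(r) {
    out <- c(if (blocks$trans) r$trans, if (blocks$gat) r$gat,
             if (blocks$kg) r$kg)
    if (is.null(out)) stop("no active representation blocks")
    out
  }
  a <- pick(repsA); b <- pick(repsB)
  c(a, b)
}

#' Initialize the classifier head
#'
#' Fully connected layers [D -> hidden... -> C] with batch normalization,
#' LeakyReLU and dropout between layers; the final layer emits C logits
#' (binary mode uses C = 2 for uniformity with the softmax output).
#'
#' @param D Input width.
#' @param C Class count (>= 2).
#' @param hidden Hidden widths.
#' @param dropout Dropout rate.
#' @return Head parameter list.
#' @export
headInit <- function(D, C, hidden = c(256L, 128L), dropout = 0.3) {
  dims <- c(D, hidden, C)
  layers <- lapply(seq_len(length(dims) - 1L), function(i) {
    lay <- list(W = .initW(dims[i], dims[i + 1L]),
                b = adParam(matrix(0, 1L, dims[i + 1L])))
    if (i < length(dims) - 1L) {
      lay$bnG <- adParam(matrix(1, 1L, dims[i + 1L]))
      lay$bnB <- adParam(matrix(0, 1L, dims[i + 1L]))
      st <- new.env(parent = emptyenv())
      st$running_mean <- rep(0, dims[i + 1L])
      st$running_var <- rep(1, dims[i + 1L])
      lay$bnState <- st
    }
    lay
  })
  list(layers = layers, dropout = dropout, C = C)
}

#' Forward pass of the classifier head
#' @param head From \code{\link{headInit}}.
#' @param X Autodiff node or numeric matrix (n x D).
#' @param training Training mode (batch statistics, dropout active).
#' @return Autodiff node of logits (n x C).
#' @export
headForward <- function(head, X, training = FALSE) {
  h <- if (is.environment(X)) X else adConst(X)
  nl <- length(head$layers)
  for (i in seq_len(nl)) {
    lay <- head$layers[[i]]
    h <- adAddBias(adMatmul(h, lay$W), lay$b)
    if (i < nl) {
      h <- adBatchNorm(h, lay$bnG, lay$bnB, lay$bnState,
                       training = training)
      h <- adLeakyRelu(h)
      h <- adDropout(h, head$dropout, training = training)
    }
  }
  h
}

#' Softmax probabilities from logits
#' @param logits Numeric matrix (n x C).
#' @return Matrix of rowwise probabilities (each row sums to 1).
#' @export
softmaxProbs <- function(logits) {
  if (is.environment(logits)) logits <- logits$value
  mx <- apply(logits, 1L, max)
  e <- exp(logits - mx)
  e / rowSums(e)
}

#' Create the full fused DDI model
#'
#' Initializes all trainable components (shared token embedding,
#' Transformer branch, GAT branch, KG aggregator, classifier head) from
#' the configuration's seed. Components outside the active ablation
#' variant are skipped.
#'
#' @param config A \code{\link{runConfig}}.
#' @param vocab A \linkS4class{Vocabulary}.
#' @param C Number of interaction classes.
#' @return Model object (list; treat as opaque).
#' @export
createModel <- function(config, vocab, C) {
  set.seed(deriveSeed(config$seed, 11L))
  blocks <- ablationBlocks(config$ablation)
  model <- list(config = config, blocks = blocks, C = as.integer(C))
  needTokens <- blocks$trans || blocks$gat
  if (needTokens) {
    model$transformer <- transformerInit(
      vocabSize(vocab), dEmb = config$dEmb, dModel = config$dModel,
      nLayers = config$nLayers, nHead = config$nHead, dFf = config$dFf)
    model$tokEmb <- model$transformer$tokEmb  # shared between branches
  }
  if (blocks$gat) {
    model$gat <- gatInit(config$dEmb, kHeads = config$kHeads,
                         dPrime = config$dPrime)
    model$P <- if (config$usePositional)
      positionalEncoding(config$L, config$dEmb,
                         damping = config$posDamping) else NULL
  }
  if (blocks$kg) {
    model$kgAgg <- kgAggregatorInit(dKg = config$dKg,
                                    channels = config$convChannels)
  }
  model$head <- headInit(pairFeatureDim(config), C,
                         hidden = config$headHidden,
                         dropout = config$dropout)
  model$params <- adCollectParams(model[c("transformer", "gat", "kgAgg",
                                          "head")])
  model$bnStates <- lapply(Filter(function(l) !is.null(l$bnState),
                                  model$head$layers), `[[`, "bnState")
  model
}

#' Snapshot the full trainable state (parameters + batch-norm statistics)
#' @keywords internal
modelSnapshot <- function(model) {
  list(params = adSnapshot(model$params),
       bn = lapply(model$bnStates, function(st)
         list(m = st$running_mean, v = st$running_var)))
}

#' @keywords internal
modelRestore <- function(model, snap) {
  adRestore(model$params, snap$params)
  for (i in seq_along(model$bnStates)) {
    model$bnStates[[i]]$running_mean <- snap$bn[[i]]$m
    model$bnStates[[i]]$running_var <- snap$bn[[i]]$v
  }
  invisible(NULL)
}

#' Precompute the static per-drug inputs
#'
#' Token sequences, molecular graphs and im2col patch matrices of the
#' subgraph embedding matrices M_d are fixed inputs: they are computed
#' once here and never recomputed per fold (frozen-feature contract).
#'
#' @param drugTable Drug table.
#' @param vocab Vocabulary.
#' @param config RunConfig.
#' @param subgraphs Named list of \linkS4class{DrugSubgraph} (required for
#'   KG-using variants).
#' @param store \linkS4class{EmbeddingStore} (required for KG variants).
#' @return Named list per drug with \code{seq}, \code{graph}, \code{cols}
#'   (patch matrix) and \code{M} (the raw S x dim matrix).
#' @export
prepareDrugInputs <- function(drugTable, vocab, config, subgraphs = NULL,
                              store = NULL) {
  blocks <- ablationBlocks(config$ablation)
  out <- vector("list", nrow(drugTable))
  names(out) <- drugTable$drug_id
  for (i in seq_len(nrow(drugTable))) {
    d <- drugTable$drug_id[i]
    prep <- list()
    seq <- encodeSmiles(drugTable$smiles[i], vocab, L = config$L,
                        caseSensitive = config$caseSensitive)
    prep$seq <- seq
    if (blocks$gat)
      prep$graph <- smilesToGraph(seq@rawTokens, L = config$L,
                                  addSelfLoops = config$selfLoops)
    if (blocks$kg) {
      if (is.null(subgraphs) || is.null(store))
        stop("KG-using variants need subgraphs and an embedding store")
      sm <- buildSubgraphMatrix(subgraphs[[d]], store)
      prep$M <- sm$M
      prep$cols <- im2col(sm$M)
    }
    out[[i]] <- prep
  }
  out
}

#' Per-drug representation nodes for a set of drugs
#'
#' Runs the active branches for each drug and stacks the results into
#' matrices (one row per drug) for the fusion stage.
#'
#' @param model From \code{\link{createModel}}.
#' @param preps From \code{\link{prepareDrugInputs}}.
#' @param drugIds Drugs to encode (rows of the output, in this order).
#' @return List of autodiff nodes \code{trans}, \code{gat}, \code{kg}
#'   (NULL for inactive blocks).
#' @keywords internal
encodeDrugs <- function(model, preps, drugIds) {
  cfg <- model$config
  b <- model$blocks
  rows <- function(fn) adStackRows(lapply(drugIds, fn))
  out <- list(trans = NULL, gat = NULL, kg = NULL)
  if (b$trans)
    out$trans <- rows(function(d)
      encodeSequence(preps[[d]]$seq, model$transformer, L = cfg$L,
                     tokEmb = model$tokEmb))
  if (b$gat)
    out$gat <- rows(function(d)
      encodeGraph(preps[[d]]$seq, preps[[d]]$graph, model$gat,
                  tokEmb = model$tokEmb, P = model$P,
                  readout = cfg$readout,
                  useEdgeWeights = cfg$useEdgeWeights))
  if (b$kg)
    out$kg <- rows(function(d) convGapProject(preps[[d]]$cols, model$kgAgg))
  out
}

#' Fused pair-feature matrix for a pair table
#' @keywords internal
pairFeatureNodes <- function(model, preps, pairs) {
  drugIds <- sort(unique(c(pairs$drug_a, pairs$drug_b)))
  Z <- encodeDrugs(model, preps, drugIds)
  sel <- function(ids) {
    S <- matrix(0, length(ids), length(drugIds))
    S[cbind(seq_along(ids), match(ids, drugIds))] <- 1
    adConst(S)
  }
  Sa <- sel(pairs$drug_a); Sb <- sel(pairs$drug_b)
  parts <- list()
  for (S in list(Sa, Sb))
    for (blk in c("trans", "gat", "kg"))
      if (!is.null(Z[[blk]]))
        parts[[length(parts) + 1L]] <- adMatmul(S, Z[[blk]])
  adConcatCols(parts)
}

#' Predict class probabilities for drug pairs
#'
#' @param model Trained model.
#' @param preps From \code{\link{prepareDrugInputs}}.
#' @param pairs data.frame with drug_a, drug_b.
#' @return n x C probability matrix (rows sum to 1).
#' @export
predictPairs <- function(model, preps, pairs) {
  adTapeBegin()
  on.exit(adTapeEnd())
  X <- pairFeatureNodes(model, preps, pairs)
  logits <- headForward(model$head, X, training = FALSE)
  softmaxProbs(logits)
}
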