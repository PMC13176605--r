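#' @import methods
NULL

#' Token vocabulary for SMILES sequences
#'
#' Maps tokens to integer IDs. The four special tokens \code{<PAD>},
#' \code{<UNK>}, \code{<CLS>} and \code{<SEP>} always occupy IDs 0--3;
#' corpus tokens follow in first-occurrence order.
#'
#' @slot tokens Character vector of all tokens in ID order (ID = position - 1).
#' @export
setClass("Vocabulary", representation(tokens = "character"))

setValidity("Vocabulary", function(object) {
  toks <- object@tokens
  if (length(toks) < 4L) return("vocabulary must contain the 4 special tokens")
  if (!identical(toks[1:4], c("<PAD>", "<UNK>", "<CLS>", "<SEP>")))
    return("special tokens must occupy the 4 lowest IDs in canonical order")
  if (anyDuplicated(toks)) return("token -> ID mapping must be injective")
  TRUE
})

#' Fixed-length integer encoding of one SMILES string
#'
#' @slot ids Integer vector of length L (vocabulary IDs, 0-based;
#'   position 1 is always \code{<CLS>}).
#' @slot mask Logical vector of length L; TRUE at real-token positions
#'   (including \code{<CLS>}), FALSE exactly at \code{<PAD>} positions.
#' @slot rawTokens Pre-padding token strings (possibly longer than L - 1
#'   when the input was truncated).
#' @export
setClass("TokenSequence",
         representation(ids = "integer", mask = "logical",
                        rawTokens = "character"))

setValidity("TokenSequence", function(object) {
  if (length(object@ids) != length(object@mask))
    return("ids and mask must have equal length")
  if (length(object@ids) < 2L) return("sequence length L must be >= 2")
  if (object@ids[1L] != 2L) return("position 1 must be <CLS> (ID 2)")
  if (any(object@mask != (object@ids != 0L)))
    return("mask must be FALSE exactly at <PAD> positions")
  TRUE
})

#' SMILES-derived molecular graph aligned to the token sequence
#'
#' Adjacency is an L x L symmetric nonnegative matrix whose row/column
#' indices are token-sequence positions (so index 1, the \code{<CLS>}
#' position, is never an atom). Edge weights follow bond multiplicities
#' (single 1, aromatic 1.5, double 2, triple 3), with optional unit
#' self-loops on atom positions.
#'
#' @slot adjacency L x L numeric matrix.
#' @slot atomMask Logical vector of length L; TRUE at atom-token positions.
#' @export
setClass("MolecularGraph",
         representation(adjacency = "matrix", atomMask = "logical"))

setValidity("MolecularGraph", function(object) {
  A <- object@adjacency
  if (nrow(A) != ncol(A)) return("adjacency must be square")
  if (length(object@atomMask) != nrow(A))
    return("atomMask length must equal adjacency dimension")
  if (any(A < 0)) return("adjacency must be nonnegative")
  if (max(abs(A - t(A))) > 1e-12) return("adjacency must be symmetric")
  bad <- which(A != 0, arr.ind = TRUE)
  if (nrow(bad) &&
      !all(object@atomMask[bad[, 1L]] & object@atomMask[bad[, 2L]]))
    return("nonzero entries allowed only between atom positions")
  TRUE
})

#' Heterogeneous knowledge graph of typed biomedical entities
#'
#' @slot nodes data.frame with columns \code{id}, \code{family}
#'   (one of Compound, Gene, Pathway, Disease, SideEffect, Other).
#' @slot triples data.frame with columns \code{head}, \code{relation},
#'   \code{tail}; parallel edges allowed (multigraph).
#' @export
setClass("HeteroKG",
         representation(nodes = "data.frame", triples = "data.frame"))

setValidity("HeteroKG", function(object) {
  if (!all(c("id", "family") %in% names(object@nodes)))
    return("nodes needs columns id, family")
  if (!all(c("head", "relation", "tail") %in% names(object@triples)))
    return("triples needs columns head, relation, tail")
  if (anyDuplicated(object@nodes$id)) return("node ids must be unique")
  ep <- unique(c(object@triples$head, object@triples$tail))
  if (!all(ep %in% object@nodes$id))
    return("every edge endpoint must be a registered node")
  TRUE
})

#' Pathway-anchored per-drug subgraph
#'
#' Houses the entity set E_d, relation-type set R_d and anchor pathways of
#' one drug; S = |E_d| + |R_d| is the row count of its embedding matrix.
#'
#' @slot drug Entity ID of the drug.
#' @slot entities Character vector E_d (includes the drug itself).
#' @slot relations Character vector R_d (distinct relation types).
#' @slot anchors Pathway-family nodes anchoring the extraction.
#' @slot triples data.frame of retained (head, relation, tail) edges.
#' @slot unreachable TRUE when no pathway was reachable within the hop
#'   limit (such drugs are removed by the consistency filter).
#' @export
setClass("DrugSubgraph",
         representation(drug = "character", entities = "character",
                        relations = "character", anchors = "character",
                        triples = "data.frame", unreachable = "logical"))

setValidity("DrugSubgraph", function(object) {
  if (length(object@drug) != 1L) return("drug must be a single ID")
  if (!object@unreachable && !(object@drug %in% object@entities))
    return("drug must belong to its own entity set")
  if (!object@unreachable && length(object@anchors) == 0L)
    return("retained drugs must have at least one anchor pathway")
  TRUE
})

#' Table of pretrained entity/relation embedding vectors
#'
#' @slot vectors Numeric matrix; one row per identifier (rownames), all
#'   rows the same dimension. Lookup of an unknown identifier is an error.
#' @export
setClass("EmbeddingStore", representation(vectors = "matrix"))

setValidity("EmbeddingStore", function(object) {
  if (is.null(rownames(object@vectors)))
    return("vectors must carry identifiers as rownames")
  if (anyDuplicated(rownames(object@vectors)))
    return("identifiers must be unique")
  TRUE
})

#' Union of two drug-centred subgraphs
#'
#' @slot drugs The two drug IDs.
#' @slot nodes data.frame with columns id, family, color
#'   (\code{"a"}, \code{"b"} or \code{"shared"}).
#' @slot triples Union edge list.
#' @slot sharedPathways Pathway nodes present in both subgraphs.
#' @slot connectedThroughPathway TRUE iff a Drug A--Pathway--Drug B
#'   bridge exists (some pathway is shared).
#' @export
setClass("MergedSubgraph",
         representation(drugs = "character", nodes = "data.frame",
                        triples = "data.frame", sharedPathways = "character",
                        connectedThroughPathway = "logical"))

## ---- generics ------------------------------------------------------------

#' Number of nodes in a graph-like object
#' @param x Object.
#' @return Integer count.
#' @export
setGeneric("nodeCount", function(x) standardGeneric("nodeCount"))

#' Number of edges in a graph-like object
#' @param x Object.
#' @return Integer count.
#' @export
setGeneric("edgeCount", function(x) standardGeneric("edgeCount"))

#' Audit counts for a pipeline stage
#'
#' Returns the (node count, edge count) pair used in the stage-by-stage
#' filtering log.
#' @param x A HeteroKG, DrugSubgraph or MergedSubgraph.
#' @return Named integer vector \code{c(nodes=, edges=)}.
#' @export
setGeneric("stageCounts", function(x) standardGeneric("stageCounts"))

#' Vocabulary size
#' @param x A Vocabulary.
#' @return Integer: number of tokens including the 4 specials.
#' @export
setGeneric("vocabSize", function(x) standardGeneric("vocabSize"))

#' Look up token IDs
#' @param x A Vocabulary.
#' @param tokens Character vector of tokens.
#' @return Integer IDs (0-based); unseen tokens map to the \code{<UNK>} ID.
#' @export
setGeneric("tokenIds", function(x, tokens) standardGeneric("tokenIds"))

#' Embedding dimension of a store
#' @param x An EmbeddingStore.
#' @export
setGeneric("embeddingDim", function(x) standardGeneric("embeddingDim"))

#' Retrieve embedding vectors by identifier
#' @param x An EmbeddingStore.
#' @param ids Character identifiers.
#' @return Matrix with one row per requested identifier.
#' @export
setGeneric("embeddingLookup", function(x, ids) standardGeneric("embeddingLookup"))

## ---- methods -------------------------------------------------------------

#' @describeIn nodeCount Nodes registered in the KG.
#' @export
setMethod("nodeCount", "HeteroKG", function(x) nrow(x@nodes))

#' @describeIn edgeCount Edges (triples) in the KG, counting multiplicity.
#' @export
setMethod("edgeCount", "HeteroKG", function(x) nrow(x@triples))

#' @describeIn stageCounts KG stage counts.
#' @export
setMethod("stageCounts", "HeteroKG", function(x)
  c(nodes = nrow(x@nodes), edges = nrow(x@triples)))

#' @describeIn nodeCount Entities in the subgraph.
#' @export
setMethod("nodeCount", "DrugSubgraph", function(x) length(x@entities))

#' @describeIn edgeCount Edges in the subgraph.
#' @export
setMethod("edgeCount", "DrugSubgraph", function(x) nrow(x@triples))

#' @describeIn stageCounts Subgraph stage counts.
#' @export
setMethod("stageCounts", "DrugSubgraph", function(x)
  c(nodes = length(x@entities), edges = nrow(x@triples)))

#' @describeIn stageCounts Merged-subgraph stage counts.
#' @export
setMethod("stageCounts", "MergedSubgraph", function(x)
  c(nodes = nrow(x@nodes), edges = nrow(x@triples)))

#' @describeIn vocabSize Token count.
#' @export
setMethod("vocabSize", "Vocabulary", function(x) length(x@tokens))

#' @describeIn tokenIds 0-based IDs with \code{<UNK>} fallback.
#' @export
setMethod("tokenIds", "Vocabulary", function(x, tokens) {
  idx <- match(tokens, x@tokens)
  idx[is.na(idx)] <- 2L  # <UNK> is position 2, ID 1
  as.integer(idx - 1L)
})

#' @describeIn embeddingDim Column count of the vector table.
#' @export
setMethod("embeddingDim", "EmbeddingStore", function(x) ncol(x@vectors))

#' @describeIn embeddingLookup Strict lookup; unknown IDs raise an error
#'   naming the first missing identifier.
#' @export
setMethod("embeddingLookup", "EmbeddingStore", function(x, ids) {
  idx <- match(ids, rownames(x@vectors))
  if (anyNA(idx)) {
    stop("identifier(s) missing from embedding store: ",
         paste(utils::head(ids[is.na(idx)], 5L), collapse = ", "))
  }
  x@vectors[idx, , drop = FALSE]
})

setMethod("show", "Vocabulary", function(object) {
  cat("Vocabulary of", length(object@tokens), "tokens",
      "(4 specials +", length(object@tokens) - 4L, "corpus tokens)\n")
})

setMethod("show", "TokenSequence", function(object) {
  cat("TokenSequence: L =", length(object@ids),
      "| real tokens =", sum(object@mask),
      "| raw =", paste(utils::head(object@rawTokens, 12L), collapse = " "),
      if (length(object@rawTokens) > 12L) "..." else "", "\n")
})

setMethod("show", "MolecularGraph", function(object) {
  nb <- (sum(object@adjacency != 0) - sum(diag(object@adjacency) != 0)) / 2
  cat("MolecularGraph: L =", nrow(object@adjacency),
      "| atoms =", sum(object@atomMask), "| bonds =", nb, "\n")
})

setMethod("show", "HeteroKG", function(object) {
  cat("HeteroKG:", nrow(object@nodes), "nodes,", nrow(object@triples),
      "edges\n")
  print(table(object@nodes$family))
})

setMethod("show", "DrugSubgraph", function(object) {
  cat("DrugSubgraph for", object@drug, ":", length(object@entities),
      "entities,", length(object@relations), "relation types,",
      length(object@anchors), "anchor pathways",
      if (object@unreachable) "[pathway-unreachable]" else "", "\n")
})

setMethod("show", "MergedSubgraph", function(object) {
  cat("MergedSubgraph of", paste(object@drugs, collapse = " + "), ":",
      nrow(object@nodes), "nodes,", nrow(object@triples), "edges;",
      length(object@sharedPathways), "shared pathway(s)\n")
})

setMethod("show", "EmbeddingStore", function(object) {
  cat("EmbeddingStore:", nrow(object@vectors), "identifiers x",
      ncol(object@vectors), "dims\n")
})
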