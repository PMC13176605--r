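## Conversion of a token sequence into a fixed-size weighted adjacency
## matrix plus position-aware node features for the GAT branch.

.bondWeights <- c("-" = 1, "=" = 2, "#" = 3, ":" = 1.5)

## atom tokens: bracket groups, Cl/Br, and letters (aromatic lowercase
## included); digits / %nn are ring closures, everything else is syntax
.isAtomToken <- function(tok) {
  grepl("^\\[", tok) | tok %in% c("Cl", "Br") | grepl("^[A-Za-z]$", tok)
}

.isAromaticAtom <- function(tok) {
  grepl("^[a-z]$", tok) | grepl("^\\[[a-z]", tok)
}

.isRingToken <- function(tok) grepl("^[0-9]$|^%[0-9]{2}$", tok)

#' Parse tokenized SMILES into a weighted adjacency matrix
#'
#' Walks the token list with standard SMILES semantics: consecutive atom
#' tokens bond with the pending bond weight (default 1; 1.5 when both atoms
#' are aromatic), bond markers \code{- = # :} set the next bond's weight
#' (1, 2, 3, 1.5), \code{(} pushes and \code{)} pops the attachment atom,
#' matching ring-closure digits (or \code{\%nn}) bond their two opening
#' atoms, and \code{.} separates disconnected components. Matrix indices
#' are token-sequence positions: position 1 is \code{<CLS>} (never an
#' atom), token i sits at position i + 1.
#'
#' @param tokens Character vector from \code{\link{smilesTokenize}}.
#' @param L Fixed matrix size; tokens beyond L - 1 are ignored (an error is
#'   raised if truncation leaves a ring closure open).
#' @param addSelfLoops Add unit self-loops on atom diagonal entries for
#'   numerical stability. Default TRUE.
#' @return A \linkS4class{MolecularGraph}.
#' @examples
#' smilesToGraph(smilesTokenize("C=C"), L = 8)
#' @export
smilesToGraph <- function(tokens, L = 128L, addSelfLoops = TRUE) {
  L <- as.integer(L)
  stopifnot(L >= 2L, is.character(tokens))
  kept <- tokens[seq_len(min(length(tokens), L - 1L))]
  A <- matrix(0, L, L)
  atomMask <- rep(FALSE, L)

  prevAtom <- NA_integer_     # position of current attachment atom
  pending <- NA_real_         # weight set by an explicit bond marker
  stack <- integer(0)
  rings <- list()             # ring label -> list(atom=, weight=)

  bond <- function(i, j, w) {
    A[i, j] <<- A[i, j] + w   # parallel closures accumulate
    A[j, i] <<- A[i, j]
  }

  for (k in seq_along(kept)) {
    tok <- kept[k]
    pos <- k + 1L
    if (.isAtomToken(tok)) {
      atomMask[pos] <- TRUE
      if (!is.na(prevAtom)) {
        w <- if (!is.na(pending)) pending
             else if (.isAromaticAtom(tok) &&
                      .isAromaticAtom(tokens[prevAtom - 1L])) 1.5
             else 1
        bond(prevAtom, pos, w)
      }
      prevAtom <- pos
      pending <- NA_real_
    } else if (tok %in% names(.bondWeights)) {
      pending <- .bondWeights[[tok]]
    } else if (.isRingToken(tok)) {
      if (is.na(prevAtom))
        stop("ring closure '", tok, "' with no preceding atom")
      if (is.null(rings[[tok]])) {
        rings[[tok]] <- list(atom = prevAtom, weight = pending)
      } else {
        open <- rings[[tok]]
        ## closing digit's own marker wins; else weight at opening; else 1
        w <- if (!is.na(pending)) pending
             else if (!is.na(open$weight)) open$weight
             else if (.isAromaticAtom(tokens[prevAtom - 1L]) &&
                      .isAromaticAtom(tokens[open$atom - 1L])) 1.5
             else 1
        bond(open$atom, prevAtom, w)
        rings[[tok]] <- NULL
      }
      pending <- NA_real_
    } else if (tok == "(") {
      stack <- c(stack, prevAtom)
    } else if (tok == ")") {
      if (length(stack) == 0L)
        stop("unmatched ')' in token stream")
      prevAtom <- stack[length(stack)]
      stack <- stack[-length(stack)]
    } else if (tok == ".") {
      prevAtom <- NA_integer_
      pending <- NA_real_
    }
    ## stereo marks (@ / \) and residual tokens: parsed, no edge
  }
  if (length(rings))
    stop("ring closure(s) opened but never closed: ",
         paste(names(rings), collapse = ", "))
  if (addSelfLoops) diag(A)[atomMask] <- diag(A)[atomMask] + 1
  methods::new("MolecularGraph", adjacency = A, atomMask = atomMask)
}

#' Damped sinusoidal positional encoding
#'
#' P[pos, 2k+1] = sin(pos / 10000^(2k/d)) * g(pos) and
#' P[pos, 2k+2] = cos(pos / 10000^(2k/d)) * g(pos) with the logistic
#' envelope g(pos) = 1 / (1 + exp(-pos / 100)), evaluated at 0-based
#' positions pos = 0 .. L-1. The default multiplicative envelope keeps
#' every entry in [-1, 1] and approaches the plain sinusoid as pos grows.
#' \code{damping = "divide"} instead divides by the envelope (the other
#' reading of the typographically ambiguous published formula); its
#' entries lie in [-2, 2].
#'
#' @param L Number of positions (rows).
#' @param d Feature width (must be even, >= 2).
#' @param damping \code{"multiply"} (default) or \code{"divide"}.
#' @return L x d numeric matrix.
#' @export
positionalEncoding <- function(L, d, damping = c("multiply", "divide")) {
  damping <- match.arg(damping)
  if (d %% 2L != 0L || d < 2L) stop("d must be even and >= 2")
  pos <- seq_len(L) - 1
  k <- seq_len(d / 2) - 1
  angle <- outer(pos, 1 / 10000^(2 * k / d))
  g <- 1 / (1 + exp(-pos / 100))
  if (damping == "divide") g <- 1 / g
  P <- matrix(0, L, d)
  P[, 2 * k + 1] <- sin(angle) * g
  P[, 2 * k + 2] <- cos(angle) * g
  P
}

#' Position-aware node features for the molecular graph
#'
#' Forms H~ = E + P at atom rows and zero elsewhere: token embeddings E are
#' zeroed at non-atom rows before the positional signal is added, so
#' non-atom and padding positions stay exactly zero.
#'
#' @param E L x d token-embedding matrix.
#' @param P L x d positional-encoding matrix (use a zero matrix, or
#'   \code{usePositional = FALSE}, for the positional-ablation mode).
#' @param atomMask Logical length-L atom indicator.
#' @param usePositional Set FALSE to drop P (ablation run mode).
#' @return L x d matrix with zero rows at non-atom positions.
#' @export
nodeFeatures <- function(E, P, atomMask, usePositional = TRUE) {
  if (!all(dim(E) == dim(P))) stop("E and P must have the same shape")
  if (length(atomMask) != nrow(E))
    stop("atomMask length must match the row count")
  H <- E
  H[!atomMask, ] <- 0
  if (usePositional) H[atomMask, ] <- H[atomMask, , drop = FALSE] +
    P[atomMask, , drop = FALSE]
  H
}

#' Dump a molecular graph as a plain-text edge list
#'
#' Debug helper for diffing against an external toolkit: one line per
#' undirected bond, \code{i j weight} with i < j (self-loops excluded).
#' @param graph A \linkS4class{MolecularGraph}.
#' @param path Optional output file; when NULL the data.frame is returned.
#' @export
edgeList <- function(graph, path = NULL) {
  A <- graph@adjacency
  idx <- which(A != 0 & upper.tri(A), arr.ind = TRUE)
  df <- data.frame(i = idx[, 1L], j = idx[, 2L], weight = A[idx])
  df <- df[order(df$i, df$j), , drop = FALSE]
  rownames(df) <- NULL
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    return(invisible(path))
  }
  df
}
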