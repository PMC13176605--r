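## SMILES tokenization, vocabulary construction and fixed-length encoding.

.specialTokens <- c("<PAD>", "<UNK>", "<CLS>", "<SEP>")

## Single compiled alternation, longest-match-first: bracket atom groups,
## two-letter halogens, %nn ring closures, then any single character
## (atoms, aromatic lowercase atoms, digits, bond markers, branches,
## stereo marks, and residual alphanumerics each become one token).
.smilesPattern <- function(caseSensitive = TRUE) {
  twoLetter <- if (caseSensitive) "Cl|Br" else "[Cc][Ll]|[Bb][Rr]"
  paste0("\\[[^]]*\\]|", twoLetter, "|%[0-9]{2}|.")
}

#' Tokenize a SMILES string
#'
#' Splits a SMILES string into chemically meaningful tokens with a single
#' regular expression: bracketed atom groups (e.g. \code{[nH]}),
#' multicharacter atom symbols (\code{Cl}, \code{Br}), two-digit
#' \code{\%nn} ring closures, and single-character tokens for atoms,
#' aromatic atoms, ring-closure digits, bond markers (\code{- = # :}),
#' branch symbols and stereo marks. The token list is a lossless cover:
#' concatenating it reproduces the input exactly.
#'
#' @param smiles Non-empty SMILES string.
#' @param caseSensitive When FALSE, \code{cl}/\code{CL} etc. are also
#'   recognized as two-letter halogens. Default TRUE (aromatic lowercase
#'   atoms are chemically distinct symbols).
#' @return Character vector of tokens.
#' @examples
#' smilesTokenize("CCO")
#' smilesTokenize("c1cc[nH]c1")
#' @export
smilesTokenize <- function(smiles, caseSensitive = TRUE) {
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(smiles))
    stop("smiles must be a single non-empty string")
  m <- gregexpr(.smilesPattern(caseSensitive), smiles, perl = TRUE)[[1]]
  toks <- regmatches(smiles, list(m))[[1]]
  ## an unterminated bracket group degrades to a bare "[" token
  if (any(toks == "["))
    stop("tokenization error: unterminated bracket group '[' in ", smiles)
  if (!identical(paste(toks, collapse = ""), smiles))
    stop("tokenization failed to cover the input losslessly")  # defensive
  toks
}

#' Build a vocabulary from a SMILES corpus
#'
#' The vocabulary is the 4 special tokens followed by all distinct tokens
#' discovered in the corpus, in first-occurrence order (deterministic for a
#' fixed corpus order). Unseen tokens encode to \code{<UNK>}.
#'
#' @param corpus Character vector of SMILES strings (non-empty).
#' @param caseSensitive Passed to \code{\link{smilesTokenize}}.
#' @return A \linkS4class{Vocabulary}.
#' @export
buildVocab <- function(corpus, caseSensitive = TRUE) {
  if (length(corpus) == 0L) stop("corpus must be non-empty")
  toks <- unlist(lapply(corpus, smilesTokenize, caseSensitive = caseSensitive),
                 use.names = FALSE)
  methods::new("Vocabulary", tokens = c(.specialTokens, unique(toks)))
}

#' Encode a SMILES string as a fixed-length ID sequence
#'
#' Prepends \code{<CLS>}, converts tokens to vocabulary IDs, then truncates
#' (keeping the prefix) or pads with \code{<PAD>} to exactly length L.
#'
#' @param smiles Non-empty SMILES string.
#' @param vocab A \linkS4class{Vocabulary}.
#' @param L Fixed sequence length (>= 2). Default 128.
#' @param caseSensitive Passed to \code{\link{smilesTokenize}}.
#' @return A \linkS4class{TokenSequence}.
#' @examples
#' v <- buildVocab(c("CCO"))
#' encodeSmiles("CCO", v, L = 8)
#' @export
encodeSmiles <- function(smiles, vocab, L = 128L, caseSensitive = TRUE) {
  stopifnot(is(vocab, "Vocabulary"))
  L <- as.integer(L)
  if (L < 2L) stop("L must be >= 2")
  raw <- smilesTokenize(smiles, caseSensitive = caseSensitive)
  kept <- raw[seq_len(min(length(raw), L - 1L))]
  ids <- c(2L, tokenIds(vocab, kept))          # <CLS> first
  ids <- c(ids, rep.int(0L, L - length(ids)))  # <PAD> tail
  methods::new("TokenSequence", ids = ids, mask = ids != 0L, rawTokens = raw)
}

#' Serialize a vocabulary to JSON
#'
#' Token-to-ID map, deterministic across runs for a fixed corpus order.
#' @param vocab A \linkS4class{Vocabulary}.
#' @param path Output file path.
#' @export
writeVocab <- function(vocab, path) {
  ids <- as.list(seq_along(vocab@tokens) - 1L)
  names(ids) <- vocab@tokens
  jsonlite::write_json(ids, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a vocabulary from JSON
#' @param path File written by \code{\link{writeVocab}}.
#' @return A \linkS4class{Vocabulary}.
#' @export
readVocab <- function(path) {
  ids <- jsonlite::read_json(path)
  toks <- names(ids)[order(unlist(ids))]
  methods::new("Vocabulary", tokens = toks)
}
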