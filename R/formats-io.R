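## Readers and writers for every external format the pipeline touches:
## DRKG-style triple TSV, delimited drug/DDI tables, whitespace-delimited
## embedding text, and JSON subgraph serialization.

.kgFamilies <- c("Compound", "Gene", "Pathway", "Disease", "SideEffect",
                 "Other")

#' Default family-prefix map for typed entity identifiers
#'
#' Entity IDs carry their family as a \code{Family::identifier} prefix
#' (DRKG convention). The map can be extended for non-DRKG inputs.
#' @return Named character vector prefix -> family.
#' @export
defaultFamilyMap <- function() {
  c("Compound" = "Compound", "Gene" = "Gene", "Pathway" = "Pathway",
    "Disease" = "Disease", "Side-effect" = "SideEffect",
    "SideEffect" = "SideEffect", "Atc" = "Other", "Tax" = "Other")
}

#' Parse the family of typed entity identifiers
#' @param ids Character IDs of the form \code{Family::identifier}.
#' @param familyMap Prefix-to-family map; unmapped prefixes become Other.
#' @return Character vector of families.
#' @export
entityFamily <- function(ids, familyMap = defaultFamilyMap()) {
  pre <- sub("::.*$", "", ids)
  fam <- unname(familyMap[pre])
  fam[is.na(fam)] <- "Other"
  fam
}

#' Read a head/relation/tail triple file
#'
#' Tab-separated, one triple per line (extra fields beyond the third are
#' ignored); blank lines are skipped. Malformed lines abort with their
#' line numbers.
#'
#' @param path Existing file path.
#' @param familyMap Prefix-to-family map for node typing.
#' @return A \linkS4class{HeteroKG} with triples in file order.
#' @export
readTriples <- function(path, familyMap = defaultFamilyMap()) {
  if (!file.exists(path)) stop("triple file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L)) {
    bad <- which(keep)[nf < 3L]
    stop("parse error: line(s) with fewer than 3 tab-separated fields: ",
         paste(utils::head(bad, 10L), collapse = ", "))
  }
  triples <- data.frame(
    head = vapply(parts, `[`, "", 1L),
    relation = vapply(parts, `[`, "", 2L),
    tail = vapply(parts, `[`, "", 3L),
    stringsAsFactors = FALSE)
  heteroKG(triples, familyMap = familyMap)
}

#' Construct a HeteroKG from a triple data.frame
#' @param triples data.frame with head, relation, tail columns.
#' @param nodes Optional node data.frame (id, family); derived from the
#'   triples' typed identifiers when omitted.
#' @param familyMap Prefix-to-family map.
#' @return A \linkS4class{HeteroKG}.
#' @export
heteroKG <- function(triples, nodes = NULL, familyMap = defaultFamilyMap()) {
  triples <- as.data.frame(triples)[, c("head", "relation", "tail")]
  if (is.null(nodes)) {
    ids <- unique(c(triples$head, triples$tail))
    nodes <- data.frame(id = ids, family = entityFamily(ids, familyMap),
                        stringsAsFactors = FALSE)
  }
  methods::new("HeteroKG", nodes = nodes, triples = triples)
}

#' Write triples as tab-separated text
#' @param kg A \linkS4class{HeteroKG}.
#' @param path Output path.
#' @export
writeTriples <- function(kg, path) {
  utils::write.table(kg@triples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.detectSep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

#' Read a drug table (drug_id, smiles)
#'
#' Comma- or tab-delimited with a header row naming the two columns
#' (delimiter auto-detected from the header line).
#' @param path File path.
#' @return data.frame with columns drug_id, smiles.
#' @export
readDrugTable <- function(path) {
  if (!file.exists(path)) stop("drug table not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = .detectSep(path),
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "", colClasses = "character")
  if (!all(c("drug_id", "smiles") %in% names(df)))
    stop("drug table must declare columns drug_id, smiles")
  df$smiles <- trimws(df$smiles)
  df$smiles[is.na(df$smiles)] <- ""
  validateDrugTable(df[, c("drug_id", "smiles")])
}

#' Validate drug-table invariants
#' @param df data.frame with drug_id, smiles.
#' @return The validated data.frame.
#' @export
validateDrugTable <- function(df) {
  if (anyDuplicated(df$drug_id))
    stop("duplicate drug_id in drug table: ",
         paste(unique(df$drug_id[duplicated(df$drug_id)]), collapse = ", "))
  if (any(!nzchar(df$smiles)))
    stop("empty SMILES for drug(s): ",
         paste(df$drug_id[!nzchar(df$smiles)], collapse = ", "))
  df
}

#' Read a DDI table (drug_a, drug_b, label)
#'
#' @param path File path (delimiter auto-detected; header required).
#' @param drugTable Optional drug table for referential validation.
#' @return data.frame with columns drug_a, drug_b, label (integer >= 0).
#' @export
readDdiTable <- function(path, drugTable = NULL) {
  if (!file.exists(path)) stop("DDI table not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = .detectSep(path),
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  if (!all(c("drug_a", "drug_b", "label") %in% names(df)))
    stop("DDI table must declare columns drug_a, drug_b, label")
  if (!is.numeric(df$label) || any(df$label != as.integer(df$label)))
    stop("DDI labels must be integers")
  df$label <- as.integer(df$label)
  if (any(df$label < 0L)) stop("DDI labels must be >= 0")
  if (!is.null(drugTable)) {
    miss <- setdiff(unique(c(df$drug_a, df$drug_b)), drugTable$drug_id)
    if (length(miss))
      stop("DDI rows reference unknown drug(s): ",
           paste(utils::head(miss, 5L), collapse = ", "))
  }
  df[, c("drug_a", "drug_b", "label")]
}

#' Write a delimited table with header
#' @param df data.frame.
#' @param path Output path; extension .tsv selects tab, otherwise comma.
#' @export
writeTable <- function(df, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an embedding table
#'
#' Whitespace-delimited text: identifier followed by its vector components,
#' one identifier per line. All rows must share one dimension.
#' @param path File path.
#' @return An \linkS4class{EmbeddingStore}.
#' @export
readEmbeddings <- function(path) {
  if (!file.exists(path)) stop("embedding file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(parts)
  if (length(unique(nf)) > 1L)
    stop("ragged embedding rows at line(s): ",
         paste(utils::head(which(nf != nf[1L]), 10L), collapse = ", "))
  ids <- vapply(parts, `[`, "", 1L)
  vec <- t(vapply(parts, function(p) as.numeric(p[-1L]),
                  numeric(nf[1L] - 1L)))
  if (anyNA(vec)) stop("non-numeric embedding component(s) in ", path)
  rownames(vec) <- ids
  methods::new("EmbeddingStore", vectors = vec)
}

#' Write an embedding store as whitespace-delimited text
#' @param store An \linkS4class{EmbeddingStore}.
#' @param path Output path.
#' @export
writeEmbeddings <- function(store, path) {
  con <- file(path, "w")
  on.exit(close(con))
  m <- store@vectors
  for (i in seq_len(nrow(m))) {
    cat(rownames(m)[i], format(m[i, ], digits = 17, trim = TRUE,
                               scientific = FALSE),
        file = con, sep = " ")
    cat("\n", file = con)
  }
  invisible(path)
}

#' Serialize a drug subgraph to JSON
#'
#' Node list with family tags plus the triple list, the drug ID, its anchor
#' pathways and the unreachable flag.
#' @param subgraph A \linkS4class{DrugSubgraph}.
#' @param path Output path.
#' @export
writeSubgraph <- function(subgraph, path) {
  fam <- entityFamily(subgraph@entities)
  obj <- list(
    drug = subgraph@drug,
    unreachable = subgraph@unreachable,
    anchors = as.list(subgraph@anchors),
    nodes = lapply(seq_along(subgraph@entities), function(i)
      list(id = subgraph@entities[i], family = fam[i])),
    relations = as.list(subgraph@relations),
    edges = unname(apply(subgraph@triples, 1L, as.list)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a drug subgraph from JSON
#' @param path File written by \code{\link{writeSubgraph}}.
#' @return A \linkS4class{DrugSubgraph}.
#' @export
readSubgraph <- function(path) {
  obj <- jsonlite::read_json(path)
  tr <- if (length(obj$edges)) {
    data.frame(head = vapply(obj$edges, function(e) e$head, ""),
               relation = vapply(obj$edges, function(e) e$relation, ""),
               tail = vapply(obj$edges, function(e) e$tail, ""),
               stringsAsFactors = FALSE)
  } else {
    data.frame(head = character(0), relation = character(0),
               tail = character(0))
  }
  methods::new("DrugSubgraph",
               drug = obj$drug,
               entities = vapply(obj$nodes, function(n) n$id, ""),
               relations = unlist(obj$relations) %||% character(0),
               anchors = unlist(obj$anchors) %||% character(0),
               triples = tr,
               unreachable = isTRUE(obj$unreachable))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
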