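## Post-hoc pathway-level interpretability: merged drug-pair subgraphs,
## shared-pathway detection, four centrality measures computed within the
## pair-specific merged subgraph, interacting-vs-noninteracting screening
## (Mann-Whitney U + Benjamini-Hochberg + Cliff's delta + direction
## consistency) and weighted-separation ranking. Everything here consumes
## model predictions and graphs only; nothing feeds back into training.

.centralityOrder <- c("betweenness", "eigenvector", "degree", "closeness")

#' Predefined centrality weights for pathway ranking
#'
#' Betweenness 0.40, eigenvector 0.30, degree 0.20, closeness 0.10
#' (weights sum to 1).
#' @return Named numeric vector in centrality order.
#' @export
repWeights <- function() {
  c(betweenness = 0.40, eigenvector = 0.30, degree = 0.20,
    closeness = 0.10)
}

#' Merge two drug-centred subgraphs
#'
#' Node/edge union with color annotations: nodes only in drug A's
#' subgraph are "a", only in B's are "b", common nodes are "shared". A
#' pathway node is shared iff it appears in both subgraphs; only then do
#' the two neighborhoods form an actual Drug A--Pathway--Drug B
#' connection, recorded in \code{connectedThroughPathway}.
#'
#' @param subA,subB \linkS4class{DrugSubgraph} objects.
#' @return A \linkS4class{MergedSubgraph}.
#' @export
mergeSubgraphs <- function(subA, subB) {
  ids <- union(subA@entities, subB@entities)
  color <- ifelse(ids %in% subA@entities & ids %in% subB@entities, "shared",
                  ifelse(ids %in% subA@entities, "a", "b"))
  nodes <- data.frame(id = ids, family = entityFamily(ids), color = color,
                      stringsAsFactors = FALSE)
  tr <- unique(rbind(subA@triples, subB@triples))
  sharedP <- nodes$id[nodes$color == "shared" & nodes$family == "Pathway"]
  methods::new("MergedSubgraph", drugs = c(subA@drug, subB@drug),
               nodes = nodes, triples = tr,
               sharedPathways = sort(sharedP),
               connectedThroughPathway = length(sharedP) > 0L)
}

#' Serialize a merged subgraph (with colors) to JSON
#' @param merged A \linkS4class{MergedSubgraph}.
#' @param path Output path.
#' @export
writeMergedSubgraph <- function(merged, path) {
  obj <- list(drugs = as.list(merged@drugs),
              sharedPathways = as.list(merged@sharedPathways),
              connectedThroughPathway = merged@connectedThroughPathway,
              nodes = unname(apply(merged@nodes, 1L, as.list)),
              edges = unname(apply(merged@triples, 1L, as.list)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Four centrality measures for selected nodes
#'
#' Degree (normalized by n - 1), betweenness (normalized by the
#' non-incident pair count), closeness in its harmonic form
#' (mean reciprocal shortest-path distance, 1/infinity = 0, so it is
#' well defined and monotone on disconnected merged subgraphs) and
#' eigenvector centrality (principal eigenvector per connected component,
#' scaled so each component's maximum entry is 1, entries nonnegative --
#' the scaling keeps scores comparable across components of different
#' sizes). The graph is treated as undirected and simple (parallel edges
#' collapsed, self-loops dropped).
#'
#' @param triples Edge data.frame (head, relation, tail) or a
#'   \linkS4class{MergedSubgraph}.
#' @param nodes Node IDs to report (default: all).
#' @return data.frame: node, degree, betweenness, closeness, eigenvector.
#' @export
nodeCentralities <- function(triples, nodes = NULL) {
  if (methods::is(triples, "MergedSubgraph")) {
    allIds <- triples@nodes$id
    triples <- triples@triples
  } else {
    allIds <- unique(c(triples$head, triples$tail))
  }
  if (length(allIds) == 0L) stop("empty graph")
  el <- triples[triples$head != triples$tail, c("head", "tail"),
                drop = FALSE]
  g <- igraph::simplify(igraph::graph_from_data_frame(
    el, directed = FALSE, vertices = allIds))
  n <- igraph::vcount(g)
  deg <- igraph::degree(g) / max(1L, n - 1L)
  btw <- igraph::betweenness(g, directed = FALSE,
                             normalized = n > 2L)
  clo <- if (n > 1L)
    igraph::harmonic_centrality(g, normalized = TRUE)
  else stats::setNames(0, igraph::V(g)$name)
  comp <- igraph::components(g)
  eig <- stats::setNames(numeric(n), igraph::V(g)$name)
  for (ci in seq_len(comp$no)) {
    vs <- names(comp$membership)[comp$membership == ci]
    if (length(vs) == 1L) {
      eig[vs] <- 1
      next
    }
    sub <- igraph::induced_subgraph(g, vs)
    ev <- abs(igraph::eigen_centrality(sub)$vector)
    ev <- ev / max(ev)
    eig[igraph::V(sub)$name] <- ev
  }
  want <- if (is.null(nodes)) igraph::V(g)$name else nodes
  miss <- setdiff(want, igraph::V(g)$name)
  if (length(miss)) stop("node(s) not in graph: ",
                         paste(miss, collapse = ", "))
  data.frame(node = want, degree = unname(deg[want]),
             betweenness = unname(btw[want]), closeness = unname(clo[want]),
             eigenvector = unname(eig[want]), stringsAsFactors = FALSE)
}

#' Cliff's delta effect size
#'
#' P(x > y) - P(x < y) over all cross-group pairs; 1 means complete
#' dominance of \code{x}.
#' @param x,y Numeric samples.
#' @return Value in [-1, 1].
#' @export
cliffsDelta <- function(x, y) {
  if (!length(x) || !length(y)) return(NA_real_)
  d <- outer(x, y, `-`)
  (sum(d > 0) - sum(d < 0)) / (length(x) * length(y))
}

#' Per-partner pathway centralities for an anchor drug
#'
#' Splits the anchor's partners into the interacting group (pairs with the
#' given label) and the noninteracting group (drugs with no recorded
#' interaction with the anchor), merges the anchor's subgraph with each
#' partner's, and records the candidate pathway's four centralities in
#' each merged subgraph. Partners whose merged subgraph does not contain
#' the pathway are recorded as non-covering and contribute no centrality
#' sample.
#'
#' @param anchor Anchor drug ID.
#' @param label Interaction class defining the interacting group.
#' @param ddiTable DDI table (used to find partners).
#' @param subgraphs Named list of \linkS4class{DrugSubgraph}.
#' @param pathway Candidate shared pathway; default: every shared pathway
#'   of the anchor's interacting merges is screened.
#' @return data.frame with columns partner, group, pathway, covered,
#'   degree, betweenness, closeness, eigenvector (NA when not covered).
#' @export
partnerGroupDistributions <- function(anchor, label, ddiTable, subgraphs,
                                      pathway = NULL) {
  inter <- unique(c(
    ddiTable$drug_b[ddiTable$drug_a == anchor & ddiTable$label == label],
    ddiTable$drug_a[ddiTable$drug_b == anchor & ddiTable$label == label]))
  touched <- unique(c(
    ddiTable$drug_b[ddiTable$drug_a == anchor & ddiTable$label > 0],
    ddiTable$drug_a[ddiTable$drug_b == anchor & ddiTable$label > 0]))
  partners <- setdiff(names(subgraphs), anchor)
  noninter <- setdiff(partners, touched)
  if (length(inter) == 0L || length(noninter) == 0L)
    stop("anchor needs >= 1 interacting and >= 1 noninteracting partner")
  anchorSub <- subgraphs[[anchor]]
  if (is.null(anchorSub)) stop("no subgraph for anchor ", anchor)
  grab <- function(partner, group) {
    sub <- subgraphs[[partner]]
    if (is.null(sub) || sub@unreachable) return(NULL)
    merged <- mergeSubgraphs(anchorSub, sub)
    paths <- if (is.null(pathway)) {
      merged@nodes$id[merged@nodes$family == "Pathway"]
    } else pathway
    if (length(paths) == 0L) return(NULL)
    present <- paths %in% merged@nodes$id
    cent <- nodeCentralities(merged, paths[present])
    out <- data.frame(partner = partner, group = group,
                      pathway = paths, covered = present,
                      degree = NA_real_, betweenness = NA_real_,
                      closeness = NA_real_, eigenvector = NA_real_,
                      stringsAsFactors = FALSE)
    if (any(present)) {
      m <- match(out$pathway[present], cent$node)
      for (col in .centralityOrder)
        out[[col]][present] <- cent[[col]][m]
    }
    out
  }
  res <- do.call(rbind, c(
    lapply(inter, grab, group = "interacting"),
    lapply(noninter, grab, group = "noninteracting")))
  res
}

#' Weighted separation score
#'
#' Fixed-weight combination of the four per-centrality separations, in
#' the order betweenness, eigenvector, degree, closeness
#' (0.40 / 0.30 / 0.20 / 0.10). Optionally multiplied by the pathway's
#' coverage and by an eigenvector-prominence bonus
#' (1 + bonus * eigenvector separation).
#'
#' @param separations Numeric length-4 vector in centrality order.
#' @param coverage Optional coverage multiplier in [0, 1].
#' @param eigenvectorBonus Bonus factor (0 disables).
#' @return Scalar score.
#' @export
weightedSeparation <- function(separations, coverage = NULL,
                               eigenvectorBonus = 0) {
  stopifnot(length(separations) == 4L)
  w <- repWeights()
  s <- sum(w * separations)
  if (!is.null(coverage)) s <- s * coverage
  if (eigenvectorBonus > 0)
    s <- s * (1 + eigenvectorBonus * max(0, separations[2L]))
  s
}

## standardized mean difference (pooled SD); 0 when both groups constant
.smd <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L) return(NA_real_)
  sp <- sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
             (nx + ny - 2))
  if (sp == 0) return(0)
  (mean(x) - mean(y)) / sp
}

#' Screen candidate pathways for interaction-specific prominence
#'
#' For each (anchor, pathway) record: (1) pathways with coverage below
#' \code{coverageMin} are dropped; (2) each centrality is compared between
#' the interacting and noninteracting samples with a two-sided
#' Mann-Whitney U test; (3) Benjamini-Hochberg correction is applied
#' across the full (pathway x centrality) hypothesis family of the
#' screen; (4) a pathway survives only if it has at least one significant
#' centrality, every significant centrality shifts positive (interacting
#' above noninteracting), and each significant centrality's Cliff's delta
#' is at least \code{deltaMin}; (5) survivors are ranked by the weighted
#' separation score of standardized mean differences, ties broken
#' lexicographically by pathway ID.
#'
#' @param records Output of \code{\link{partnerGroupDistributions}} (one
#'   anchor; multiple pathways allowed).
#' @param coverageMin Minimum fraction of interacting partners whose
#'   merged subgraph contains the pathway (default 0.3).
#' @param alpha BH false-discovery-rate level (default 0.05).
#' @param deltaMin Minimum Cliff's delta for significant centralities
#'   (default 0.147, the conventional "small"-effect bound).
#' @param coverageWeight Multiply the ranking score by coverage.
#' @param eigenvectorBonus See \code{\link{weightedSeparation}}.
#' @return data.frame, one row per screened pathway, ordered by rank:
#'   pathway, coverage, per-centrality p/q/delta/smd, nSignificant,
#'   allPositive, passed, score. Attribute \code{"skipped"} lists
#'   pathways whose groups were too small to test.
#' @export
screenPathways <- function(records, coverageMin = 0.3, alpha = 0.05,
                           deltaMin = 0.147, coverageWeight = FALSE,
                           eigenvectorBonus = 0) {
  if (is.null(records) || nrow(records) == 0L) stop("no screening records")
  pathways <- sort(unique(records$pathway))
  rows <- list()
  skipped <- character(0)
  for (pw in pathways) {
    rec <- records[records$pathway == pw, , drop = FALSE]
    intAll <- rec[rec$group == "interacting", , drop = FALSE]
    cov <- mean(intAll$covered)
    if (!is.finite(cov) || cov < coverageMin) next
    int <- intAll[intAll$covered, , drop = FALSE]
    non <- rec[rec$group == "noninteracting" & rec$covered, , drop = FALSE]
    if (nrow(int) < 2L || nrow(non) < 2L) {
      skipped <- c(skipped, pw)
      next
    }
    row <- list(pathway = pw, coverage = cov)
    for (cn in .centralityOrder) {
      x <- int[[cn]]; y <- non[[cn]]
      p <- suppressWarnings(
        stats::wilcox.test(x, y, exact = FALSE)$p.value)
      if (is.nan(p)) p <- 1  # identical constant samples
      row[[paste0(cn, "_p")]] <- p
      row[[paste0(cn, "_delta")]] <- cliffsDelta(x, y)
      row[[paste0(cn, "_smd")]] <- .smd(x, y)
    }
    rows[[length(rows) + 1L]] <- as.data.frame(row,
                                               stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    out <- data.frame(pathway = character(0))
    attr(out, "skipped") <- skipped
    return(out)
  }
  out <- do.call(rbind, rows)
  pCols <- paste0(.centralityOrder, "_p")
  pAll <- as.matrix(out[, pCols, drop = FALSE])
  qAll <- matrix(stats::p.adjust(pAll, method = "BH"), nrow(out))
  colnames(qAll) <- paste0(.centralityOrder, "_q")
  out <- cbind(out, qAll)
  sig <- qAll <= alpha
  deltas <- as.matrix(out[, paste0(.centralityOrder, "_delta"),
                          drop = FALSE])
  smds <- as.matrix(out[, paste0(.centralityOrder, "_smd"), drop = FALSE])
  out$nSignificant <- rowSums(sig)
  out$allPositive <- vapply(seq_len(nrow(out)), function(i)
    all(deltas[i, sig[i, ]] > 0), TRUE)
  out$passed <- out$nSignificant > 0 & out$allPositive &
    vapply(seq_len(nrow(out)), function(i)
      all(deltas[i, sig[i, ]] >= deltaMin), TRUE)
  out$score <- vapply(seq_len(nrow(out)), function(i)
    weightedSeparation(ifelse(is.na(smds[i, ]), 0, smds[i, ]),
                       coverage = if (coverageWeight) out$coverage[i],
                       eigenvectorBonus = eigenvectorBonus), 0)
  out <- out[order(-out$passed, -out$score, out$pathway), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Distribution summary for centrality score plots
#'
#' Kernel-density summaries of the interacting and noninteracting
#' centrality samples, the pooled 95th percentile (quantile type 7) and
#' the rug of observations above it. These are descriptive visual
#' summaries, not inferential tests. Constant samples fall back to a
#' histogram summary with a warning.
#'
#' @param interacting,noninteracting Numeric samples (>= 2 points each).
#' @param percentile Marker percentile (default 0.95).
#' @return List with \code{density} (per group), \code{threshold},
#'   \code{rug} (observations above the threshold), \code{meanDiff} and
#'   \code{fallback}.
#' @export
distributionSummary <- function(interacting, noninteracting,
                                percentile = 0.95) {
  if (length(interacting) < 2L || length(noninteracting) < 2L)
    stop("each group needs >= 2 points")
  pooled <- c(interacting, noninteracting)
  thr <- unname(stats::quantile(pooled, percentile, type = 7))
  summarise <- function(x) {
    if (stats::sd(x) == 0) {
      warning("constant sample; falling back to histogram summary")
      h <- graphics::hist(x, plot = FALSE)
      list(x = h$mids, y = h$density, fallback = TRUE)
    } else {
      d <- stats::density(x)
      list(x = d$x, y = d$y, fallback = FALSE)
    }
  }
  int <- summarise(interacting)
  non <- summarise(noninteracting)
  list(density = list(interacting = int, noninteracting = non),
       threshold = thr, rug = pooled[pooled > thr],
       meanDiff = mean(interacting) - mean(noninteracting),
       fallback = int$fallback || non$fallback)
}

#' Plot a centrality distribution summary
#'
#' Writes a PNG with the two density curves, the percentile marker as a
#' vertical dashed line and a rug of high-scoring observations.
#' @param summary From \code{\link{distributionSummary}}.
#' @param path Output PNG path.
#' @param main Plot title.
#' @export
plotDistributionSummary <- function(summary, path, main = "") {
  grDevices::png(path, width = 720, height = 480)
  on.exit(grDevices::dev.off())
  xs <- range(summary$density$interacting$x, summary$density$noninteracting$x,
              summary$threshold)
  ys <- range(0, summary$density$interacting$y,
              summary$density$noninteracting$y)
  graphics::plot(NA, xlim = xs, ylim = ys, xlab = "centrality score",
                 ylab = "density", main = main)
  graphics::lines(summary$density$interacting$x,
                  summary$density$interacting$y, col = "red", lwd = 2)
  graphics::lines(summary$density$noninteracting$x,
                  summary$density$noninteracting$y, col = "blue", lwd = 2)
  graphics::abline(v = summary$threshold, lty = 2)
  if (length(summary$rug)) graphics::rug(summary$rug)
  graphics::legend("topright", legend = c("interacting", "noninteracting"),
                   col = c("red", "blue"), lwd = 2, bty = "n")
  invisible(path)
}
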