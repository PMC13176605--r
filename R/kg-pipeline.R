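## Heterogeneous-KG preprocessing: entity-family filtering, random-walk
## neighborhood sampling with restart, pathway-anchored 4-hop subgraph
## extraction, and DDI/SMILES consistency filtering. All hop and
## shortest-path computations treat the KG as undirected; parallel edges
## are allowed but hop counting uses the simple-graph projection.

.kgIgraph <- function(kg) {
  igraph::graph_from_data_frame(
    kg@triples[, c("head", "tail")], directed = FALSE,
    vertices = kg@nodes$id)
}

#' Filter a KG to the retained entity families
#'
#' CGPDS keeps Compound, Gene, Pathway, Disease and SideEffect nodes;
#' CGPD additionally drops SideEffect. An edge survives only if both
#' endpoints survive; surviving nodes are retained even when isolated.
#'
#' @param kg A \linkS4class{HeteroKG}.
#' @param variant \code{"CGPDS"} or \code{"CGPD"}.
#' @return The filtered \linkS4class{HeteroKG}.
#' @export
filterFamilies <- function(kg, variant = c("CGPDS", "CGPD")) {
  variant <- match.arg(variant)
  fams <- c("Compound", "Gene", "Pathway", "Disease",
            if (variant == "CGPDS") "SideEffect")
  nodes <- kg@nodes[kg@nodes$family %in% fams, , drop = FALSE]
  keep <- kg@triples$head %in% nodes$id & kg@triples$tail %in% nodes$id
  methods::new("HeteroKG", nodes = nodes,
               triples = kg@triples[keep, , drop = FALSE])
}

#' Attach self-loops to edge-less drugs
#'
#' Every listed drug present in the KG with zero incident edges gains one
#' \code{(drug, self, drug)} loop so the random walk has a defined move;
#' drugs that already have edges are unchanged.
#'
#' @param kg A \linkS4class{HeteroKG}.
#' @param drugs Character vector of drug entity IDs.
#' @return The augmented \linkS4class{HeteroKG}.
#' @export
attachSelfLoops <- function(kg, drugs) {
  drugs <- intersect(drugs, kg@nodes$id)
  touched <- unique(c(kg@triples$head, kg@triples$tail))
  lonely <- setdiff(drugs, touched)
  if (length(lonely) == 0L) return(kg)
  loops <- data.frame(head = lonely, relation = "self", tail = lonely,
                      stringsAsFactors = FALSE)
  methods::new("HeteroKG", nodes = kg@nodes,
               triples = rbind(kg@triples, loops))
}

#' Random-walk-with-restart neighborhood of a seed drug
#'
#' Runs \code{iterations} independent walks of at most \code{steps}
#' transitions from the seed. At each transition the walker restarts to
#' the seed with probability \code{restartProb}, otherwise moves to a
#' uniformly random neighbor (incident edges, relation-agnostic). Distinct
#' visited nodes accumulate until the \code{spread} budget is reached.
#' Each walk draws from its own seed derived from \code{rngSeed}, so
#' halving \code{steps} or \code{iterations} explores a deterministic
#' subset of the full-budget neighborhood.
#'
#' @param kg A \linkS4class{HeteroKG} (after self-loop attachment).
#' @param seedDrug Seed entity ID; must have at least one incident edge.
#' @param steps,restartProb,iterations,spread Walk budgets.
#' @param rngSeed Integer seed.
#' @return \linkS4class{HeteroKG} induced on the visited nodes.
#' @export
randomWalkNeighborhood <- function(kg, seedDrug, steps = 200L,
                                   restartProb = 0.3, iterations = 100L,
                                   spread = 10000L, rngSeed = 1L) {
  if (!seedDrug %in% kg@nodes$id) stop("seed drug not in KG: ", seedDrug)
  ends <- c(kg@triples$head, kg@triples$tail)
  if (!seedDrug %in% ends)
    stop("seed drug has no incident edge (attach self-loops first): ",
         seedDrug)
  nbr <- split(c(kg@triples$tail, kg@triples$head), ends)
  visited <- new.env(parent = emptyenv())
  assign(seedDrug, TRUE, envir = visited)
  nVisited <- 1L
  for (it in seq_len(iterations)) {
    if (nVisited >= spread) break
    set.seed(deriveSeed(rngSeed, it))
    cur <- seedDrug
    for (s in seq_len(steps)) {
      if (stats::runif(1) < restartProb) {
        cur <- seedDrug
        next
      }
      nb <- nbr[[cur]]
      if (is.null(nb)) { cur <- seedDrug; next }
      cur <- nb[[sample.int(length(nb), 1L)]]
      if (!exists(cur, envir = visited, inherits = FALSE)) {
        assign(cur, TRUE, envir = visited)
        nVisited <- nVisited + 1L
        if (nVisited >= spread) break
      }
    }
  }
  vis <- ls(visited)
  keep <- kg@triples$head %in% vis & kg@triples$tail %in% vis
  methods::new("HeteroKG",
               nodes = kg@nodes[kg@nodes$id %in% vis, , drop = FALSE],
               triples = kg@triples[keep, , drop = FALSE])
}

#' Pathway-anchored hop-limited subgraph extraction
#'
#' Anchors are the pathway-family nodes of the neighborhood; a node is
#' retained iff its undirected shortest-path distance to the nearest
#' anchor is at most \code{hopLimit}. When the neighborhood contains no
#' pathway, the result is flagged pathway-unreachable (not an error), and
#' likewise when the drug itself falls outside the hop limit.
#'
#' @param neighborhood \linkS4class{HeteroKG} from
#'   \code{\link{randomWalkNeighborhood}}.
#' @param drug The seed drug's entity ID.
#' @param hopLimit Maximum hops to the nearest anchor pathway (default 4).
#' @return A \linkS4class{DrugSubgraph}.
#' @export
pathwayAnchoredExtract <- function(neighborhood, drug, hopLimit = 4L) {
  anchors <- neighborhood@nodes$id[neighborhood@nodes$family == "Pathway"]
  flagUnreachable <- function() {
    methods::new("DrugSubgraph", drug = drug, entities = character(0),
                 relations = character(0), anchors = character(0),
                 triples = neighborhood@triples[0, , drop = FALSE],
                 unreachable = TRUE)
  }
  if (length(anchors) == 0L) return(flagUnreachable())
  g <- .kgIgraph(neighborhood)
  d <- igraph::distances(g, v = anchors, mode = "all")
  minDist <- apply(d, 2L, min)
  keep <- names(minDist)[minDist <= hopLimit]
  if (!drug %in% keep) return(flagUnreachable())
  tr <- neighborhood@triples
  tr <- tr[tr$head %in% keep & tr$tail %in% keep, , drop = FALSE]
  methods::new("DrugSubgraph", drug = drug,
               entities = sort(keep),
               relations = sort(unique(tr$relation)),
               anchors = sort(intersect(anchors, keep)),
               triples = tr, unreachable = FALSE)
}

#' Wrap a raw random-walk neighborhood as a drug subgraph
#'
#' Used by the run modes that embed the whole walk neighborhood without
#' the pathway-anchored shortest-path extraction. Anchors are the pathway
#' nodes present in the neighborhood (possibly none; the subgraph is then
#' flagged unreachable).
#'
#' @param neighborhood \linkS4class{HeteroKG} from
#'   \code{\link{randomWalkNeighborhood}}.
#' @param drug Seed drug ID.
#' @return A \linkS4class{DrugSubgraph}.
#' @export
neighborhoodSubgraph <- function(neighborhood, drug) {
  anchors <- neighborhood@nodes$id[neighborhood@nodes$family == "Pathway"]
  unreachable <- length(anchors) == 0L || !drug %in% neighborhood@nodes$id
  methods::new("DrugSubgraph", drug = drug,
               entities = if (unreachable) character(0)
                          else sort(neighborhood@nodes$id),
               relations = if (unreachable) character(0)
                           else sort(unique(neighborhood@triples$relation)),
               anchors = sort(anchors),
               triples = neighborhood@triples,
               unreachable = unreachable)
}

#' Per-drug subgraph construction for a whole drug table
#'
#' Convenience wrapper: family filtering, self-loop attachment, one
#' random-walk neighborhood and one pathway-anchored extraction per drug.
#' Walk seeds derive deterministically from \code{config$seed} and the
#' drug's position.
#'
#' @param kg Raw \linkS4class{HeteroKG}.
#' @param drugTable Drug table (drug_id, smiles); drug IDs must match
#'   Compound entity IDs.
#' @param config A \code{\link{runConfig}}.
#' @param keepNeighborhoods Also return the raw walk neighborhoods
#'   (wrapped as subgraphs) as attribute \code{"rwSubgraphs"}.
#' @return Named list of \linkS4class{DrugSubgraph} objects plus the
#'   stage-count log as attribute \code{"stageLog"}.
#' @export
drugSubgraphs <- function(kg, drugTable, config = runConfig(),
                          keepNeighborhoods = FALSE) {
  log <- data.frame(stage = "initial", nodes = nodeCount(kg),
                    edges = edgeCount(kg))
  fkg <- filterFamilies(kg, config$variant)
  log <- rbind(log, data.frame(
    stage = paste0("after filtering (", config$variant, ")"),
    nodes = nodeCount(fkg), edges = edgeCount(fkg)))
  fkg <- attachSelfLoops(fkg, drugTable$drug_id)
  subs <- rw <- vector("list", nrow(drugTable))
  names(subs) <- names(rw) <- drugTable$drug_id
  walkCounts <- finalCounts <- matrix(0, nrow(drugTable), 2L)
  for (i in seq_len(nrow(drugTable))) {
    d <- drugTable$drug_id[i]
    if (!d %in% fkg@nodes$id) {
      subs[[i]] <- methods::new(
        "DrugSubgraph", drug = d, entities = character(0),
        relations = character(0), anchors = character(0),
        triples = fkg@triples[0, , drop = FALSE], unreachable = TRUE)
      next
    }
    nb <- randomWalkNeighborhood(
      fkg, d, steps = config$walkSteps, restartProb = config$walkRestart,
      iterations = config$walkIterations, spread = config$walkSpread,
      rngSeed = deriveSeed(config$seed, 7000L + i))
    walkCounts[i, ] <- stageCounts(nb)
    if (keepNeighborhoods) rw[[i]] <- neighborhoodSubgraph(nb, d)
    subs[[i]] <- pathwayAnchoredExtract(nb, d, config$hopLimit)
    finalCounts[i, ] <- stageCounts(subs[[i]])
  }
  log <- rbind(log,
    data.frame(stage = "random walk (mean)",
               nodes = mean(walkCounts[, 1L]),
               edges = mean(walkCounts[, 2L])),
    data.frame(stage = sprintf("final (%d-hop, mean)", config$hopLimit),
               nodes = mean(finalCounts[, 1L]),
               edges = mean(finalCounts[, 2L])))
  attr(subs, "stageLog") <- log
  if (keepNeighborhoods) attr(subs, "rwSubgraphs") <- rw
  subs
}

#' DDI/SMILES consistency filtering
#'
#' Removes drugs whose subgraph has no usable edges or is flagged
#' pathway-unreachable, and drops every DDI row touching a removed drug.
#'
#' @param drugTable Drug table.
#' @param ddiTable DDI table.
#' @param subgraphs Named list of \linkS4class{DrugSubgraph} (one per drug).
#' @return List with \code{drugs}, \code{ddis} and a \code{removals}
#'   data.frame (drug_id, reason).
#' @export
consistencyFilter <- function(drugTable, ddiTable, subgraphs) {
  reasons <- character(0)
  removed <- character(0)
  for (d in drugTable$drug_id) {
    sg <- subgraphs[[d]]
    if (is.null(sg)) stop("no subgraph computed for drug ", d)
    if (sg@unreachable) {
      removed <- c(removed, d)
      reasons <- c(reasons, "no pathway reachable within the hop limit")
    } else if (nrow(sg@triples) == 0L) {
      removed <- c(removed, d)
      reasons <- c(reasons, "no usable edges after filtering")
    }
  }
  drugs <- drugTable[!drugTable$drug_id %in% removed, , drop = FALSE]
  ddis <- ddiTable[!(ddiTable$drug_a %in% removed |
                     ddiTable$drug_b %in% removed), , drop = FALSE]
  if (nrow(drugs) == 0L)
    warning("all drugs removed by the consistency filter")
  list(drugs = drugs, ddis = ddis,
       removals = data.frame(drug_id = removed, reason = reasons,
                             stringsAsFactors = FALSE))
}

#' Undirected hop distance from a drug to its nearest anchor pathway
#'
#' Independent audit helper used to verify the post-extraction guarantee.
#' @param subgraph A \linkS4class{DrugSubgraph}.
#' @return Integer distance (Inf when unreachable).
#' @export
anchorDistance <- function(subgraph) {
  if (subgraph@unreachable || length(subgraph@anchors) == 0L) return(Inf)
  g <- igraph::graph_from_data_frame(
    subgraph@triples[, c("head", "tail")], directed = FALSE,
    vertices = subgraph@entities)
  d <- igraph::distances(g, v = subgraph@drug, to = subgraph@anchors,
                         mode = "all")
  min(d)
}
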