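## Seeded synthetic-data generators. They emulate the pipeline's four
## inputs -- drug SMILES, typed KG triples with planted Drug--Gene--
## Pathway--Gene--Drug mediator motifs, DDI labels correlated with planted
## pathway sharing, and near-translational embedding stores -- so every
## module is exercisable end-to-end without external downloads.

#' Specification for the synthetic study conditions
#'
#' @param nDrugs Number of drugs.
#' @param nPathways Shared (plantable) pathways.
#' @param nGenes Gene pool size.
#' @param nDiseases,nSideEffects Decoy entity counts.
#' @param mediatorDensity Fraction of drug pairs receiving a planted
#'   bridging pathway (Drug--Gene--Pathway--Gene--Drug motif).
#' @param nClasses Interaction classes (class 0 = no planted mediator).
#' @param noise Label-flip probability, in [0, 0.5).
#' @param embDim Embedding dimension of the synthetic store (32 keeps
#'   tests fast; set 400 for shape-fidelity checks).
#' @param nUnreachable Extra drugs wired to their nearest pathway through
#'   a 5-hop gene chain only (they must be flagged pathway-unreachable by
#'   a 4-hop extraction).
#' @param decoyEdgeProb Probability of a decoy Gene--Disease /
#'   Gene--SideEffect edge per gene.
#' @param seed Master seed.
#' @return Object of class \code{SyntheticSpec} (named list).
#' @export
syntheticSpec <- function(nDrugs = 50L, nPathways = 8L, nGenes = 120L,
                          nDiseases = 10L, nSideEffects = 10L,
                          mediatorDensity = 0.3, nClasses = 5L,
                          noise = 0, embDim = 32L, nUnreachable = 0L,
                          decoyEdgeProb = 0.3, seed = 1L) {
  spec <- mget(names(formals()))
  stopifnot(spec$nDrugs >= 2L, spec$nPathways >= 1L, spec$nGenes >= 1L,
            spec$noise >= 0, spec$noise < 0.5, spec$embDim >= 2L,
            spec$mediatorDensity >= 0, spec$mediatorDensity <= 1)
  structure(spec, class = "SyntheticSpec")
}

.drugIds <- function(n) sprintf("Compound::D%03d", seq_len(n))

#' Generate a typed synthetic knowledge graph with planted mediators
#'
#' Every drug gets a private attachment (drug -- gene -- private pathway)
#' so it is pathway-reachable without sharing. For each planted pair a
#' shared pathway bridges the two drugs through dedicated genes:
#' Drug A -- Gene -- Pathway -- Gene -- Drug B (2 hops per side, within a
#' 4-hop extraction). Decoy Gene--Disease and Gene--SideEffect edges add
#' heterogeneous clutter without creating additional drug--pathway--drug
#' connections. Unreachable drugs are attached through a 5-gene chain so
#' their nearest pathway sits at 5 hops.
#'
#' @param spec A \code{\link{syntheticSpec}}.
#' @return A \linkS4class{HeteroKG} with attribute \code{"truth"}: a
#'   data.frame (drug_a, drug_b, pathway) of planted mediators.
#' @export
genKg <- function(spec = syntheticSpec()) {
  set.seed(deriveSeed(spec$seed, 101L))
  drugs <- .drugIds(spec$nDrugs)
  paths <- sprintf("Pathway::P%03d", seq_len(spec$nPathways))
  genes <- sprintf("Gene::G%04d", seq_len(spec$nGenes))
  dis <- sprintf("Disease::I%03d", seq_len(spec$nDiseases))
  se <- sprintf("Side-effect::S%03d", seq_len(spec$nSideEffects))
  tr <- list()
  add <- function(h, r, t) tr[[length(tr) + 1L]] <<-
    data.frame(head = h, relation = r, tail = t, stringsAsFactors = FALSE)
  ## private reachability: drug - gene - private pathway
  privPath <- sprintf("Pathway::PRIV%03d", seq_len(spec$nDrugs))
  privGene <- sprintf("Gene::GPRIV%03d", seq_len(spec$nDrugs))
  add(drugs, "compound_gene", privGene)
  add(privGene, "gene_pathway", privPath)
  ## planted mediator motifs
  pairs <- t(utils::combn(spec$nDrugs, 2L))
  nPlant <- floor(spec$mediatorDensity * nrow(pairs))
  if (nPlant > nrow(pairs)) stop("more planted pairs than drug pairs")
  truth <- data.frame(drug_a = character(0), drug_b = character(0),
                      pathway = character(0))
  if (nPlant > 0L) {
    sel <- pairs[sample.int(nrow(pairs), nPlant), , drop = FALSE]
    pw <- paths[(seq_len(nPlant) - 1L) %% spec$nPathways + 1L]
    gA <- sprintf("Gene::GBRA%04d", seq_len(nPlant))
    gB <- sprintf("Gene::GBRB%04d", seq_len(nPlant))
    add(drugs[sel[, 1L]], "compound_gene", gA)
    add(gA, "gene_pathway", pw)
    add(pw, "pathway_gene", gB)
    add(gB, "gene_compound", drugs[sel[, 2L]])
    truth <- data.frame(drug_a = drugs[sel[, 1L]], drug_b = drugs[sel[, 2L]],
                        pathway = pw, stringsAsFactors = FALSE)
  }
  ## decoy heterogeneity on the gene pool
  nDecoy <- stats::rbinom(1L, spec$nGenes, spec$decoyEdgeProb)
  if (nDecoy > 0L) {
    gd <- sample(genes, nDecoy, replace = TRUE)
    add(gd, "gene_disease", sample(dis, nDecoy, replace = TRUE))
    gs <- sample(genes, nDecoy, replace = TRUE)
    add(gs, "gene_sideeffect", sample(se, nDecoy, replace = TRUE))
  }
  ## pathway-unreachable drugs: 5-hop gene chain to a pathway
  if (spec$nUnreachable > 0L) {
    for (u in seq_len(spec$nUnreachable)) {
      ## drug - g1 - g2 - g3 - g4 - pathway: nearest pathway at 5 hops
      ud <- sprintf("Compound::DU%02d", u)
      chain <- sprintf("Gene::GU%02d_%d", u, 1:4)
      add(c(ud, chain[-4L]), "compound_gene", chain)
      add(chain[4L], "gene_pathway", paths[1L])
    }
  }
  triples <- do.call(rbind, tr)
  allIds <- unique(c(triples$head, triples$tail, drugs, paths, genes, dis,
                     se))
  kg <- heteroKG(triples,
                 nodes = data.frame(id = allIds,
                                    family = entityFamily(allIds),
                                    stringsAsFactors = FALSE))
  attr(kg, "truth") <- truth
  kg
}

.smilesPanel <- c(
  "CC(=O)Oc1ccccc1C(=O)O",            # aspirin
  "CN1C(=O)N(C)c2ncn(C)c2C1=O",       # caffeine
  "CC(C)Cc1ccc(cc1)C(C)C(=O)O",       # ibuprofen
  "CC(=O)Nc1ccc(O)cc1",               # paracetamol
  "Clc1ccccc1",                        # chlorobenzene
  "BrCCBr",                            # dibromoethane
  "c1cc[nH]c1",                        # pyrrole
  "C1CC1",                             # cyclopropane
  "C=C",                               # ethene
  "C#N",                               # hydrogen cyanide
  "CC(C)C",                            # isobutane
  "c1ccncc1",                          # pyridine
  "OC(=O)c1ccccc1O",                   # salicylic acid
  "CCOC(=O)C",                         # ethyl acetate
  "C1=CC2=CC=CC=C2C=C1",               # naphthalene (uppercase aromatic)
  "CN(C)C(=N)N=C(N)N",                 # metformin
  "NC(=O)c1ccncc1",                    # isonicotinamide
  "OCC(O)CO",                          # glycerol
  "CC(N)Cc1ccccc1",                    # amphetamine
  "[Na+].[Cl-]"                        # salt (dot-disconnected, brackets)
)

#' Fixed fixture panel of real drug-like SMILES
#'
#' Includes multicharacter halogens, bracket atoms, aromatic rings, ring
#' closures, branches and a dot-disconnected salt.
#' @return Character vector of 20 SMILES.
#' @export
smilesPanel <- function() .smilesPanel

#' Generate a synthetic drug table
#'
#' The 20-string fixture panel first, then random syntactically valid
#' SMILES drawn from a small grammar over C/c/N/O/S/Cl/Br with optional
#' ring closures, branches, bond markers and bracket atoms. Every emitted
#' string round-trips through the tokenizer (lossless cover).
#'
#' @param n Number of drugs (>= 1).
#' @param rngSeed Integer seed.
#' @param ids Drug IDs (default \code{Compound::Dxxx} to match
#'   \code{\link{genKg}}).
#' @return Drug table data.frame (drug_id, smiles), unique SMILES.
#' @export
genSmiles <- function(n, rngSeed = 1L, ids = .drugIds(n)) {
  stopifnot(n >= 1L, length(ids) == n)
  set.seed(deriveSeed(rngSeed, 202L))
  atoms <- c("C", "N", "O", "S", "Cl", "Br", "c")
  brackets <- c("[nH]", "[O-]", "[N+]")
  bonds <- c("", "", "", "=", "#")
  randSmiles <- function() {
    len <- sample(3:9, 1L)
    useRing <- stats::runif(1) < 0.4
    parts <- character(0)
    for (i in seq_len(len)) {
      a <- if (stats::runif(1) < 0.08) sample(brackets, 1L)
           else sample(atoms, 1L, prob = c(6, 2, 2, 1, 1, 1, 0))
      b <- if (i > 1L) sample(bonds, 1L) else ""
      if (b %in% c("=", "#") && grepl("Cl|Br|\\[", a)) b <- ""
      parts <- c(parts, b, a)
      if (i == 2L && stats::runif(1) < 0.3) {
        inner <- paste(sample(c("C", "O", "N"), sample(1:3, 1L),
                              replace = TRUE), collapse = "")
        parts <- c(parts, "(", inner, ")")
      }
    }
    s <- paste(parts, collapse = "")
    if (useRing) s <- paste0("C1", gsub("=|#", "", s), "C1")
    s
  }
  out <- character(0)
  while (length(out) < n) {
    cand <- if (length(out) < min(n, length(.smilesPanel)))
      .smilesPanel[length(out) + 1L] else randSmiles()
    ok <- tryCatch(identical(
      paste(smilesTokenize(cand), collapse = ""), cand),
      error = function(e) FALSE)
    if (ok && !cand %in% out) out <- c(out, cand)
  }
  data.frame(drug_id = ids, smiles = out, stringsAsFactors = FALSE)
}

#' Generate DDI labels from the planted KG truth
#'
#' Planted pairs get class 1 + (planted-pathway index mod (nClasses - 1));
#' sampled non-planted pairs get class 0. Labels are then flipped to a
#' uniformly random other class with probability \code{noise}. The result
#' mixes all planted pairs with enough negatives to reach \code{nPairs}
#' rows (fewer when the drug set is too small).
#'
#' @param kg KG from \code{\link{genKg}} (carrying its truth attribute),
#'   or the truth data.frame itself.
#' @param spec The \code{\link{syntheticSpec}} used to build the KG.
#' @param nPairs Total DDI rows wanted (default 200).
#' @return DDI table (drug_a, drug_b, label) with attribute
#'   \code{"classCounts"}.
#' @export
genDdi <- function(kg, spec = syntheticSpec(), nPairs = 200L) {
  truth <- if (is.data.frame(kg)) kg else attr(kg, "truth")
  if (is.null(truth)) stop("kg carries no planted-truth record")
  set.seed(deriveSeed(spec$seed, 303L))
  drugs <- .drugIds(spec$nDrugs)
  ## every planted pair stays excluded from the negative pool, even when
  ## the table is subsampled to honor the requested size
  planted <- paste(pmin(truth$drug_a, truth$drug_b),
                   pmax(truth$drug_a, truth$drug_b))
  if (nrow(truth) > nPairs)
    truth <- truth[sort(sample.int(nrow(truth), nPairs)), , drop = FALSE]
  pwIdx <- as.integer(sub("^Pathway::P", "", truth$pathway))
  lab <- if (nrow(truth)) 1L + (pwIdx - 1L) %% (spec$nClasses - 1L)
         else integer(0)
  ddi <- data.frame(drug_a = truth$drug_a, drug_b = truth$drug_b,
                    label = lab, stringsAsFactors = FALSE)
  allPairs <- t(utils::combn(drugs, 2L))
  key <- paste(allPairs[, 1L], allPairs[, 2L])
  free <- which(!key %in% planted)
  nNeg <- min(length(free), max(0L, nPairs - nrow(ddi)))
  if (nNeg > 0L) {
    sel <- free[sample.int(length(free), nNeg)]
    ddi <- rbind(ddi, data.frame(drug_a = allPairs[sel, 1L],
                                 drug_b = allPairs[sel, 2L], label = 0L,
                                 stringsAsFactors = FALSE))
  }
  if (spec$noise > 0) {
    flip <- stats::runif(nrow(ddi)) < spec$noise
    if (any(flip)) {
      ddi$label[flip] <- vapply(ddi$label[flip], function(l)
        sample(setdiff(0:(spec$nClasses - 1L), l), 1L), 0L)
    }
  }
  rownames(ddi) <- NULL
  attr(ddi, "classCounts") <- table(factor(ddi$label,
                                           levels = 0:(spec$nClasses - 1L)))
  ddi
}

#' Generate a synthetic embedding store for a KG
#'
#' Random mode: i.i.d. Gaussian vectors for every entity and relation
#' type. Translational mode: relation vectors are drawn first, and each
#' entity's vector is pinned to head + relation + small noise the first
#' time it appears as a tail (a spanning set of exact translations), so
#' h + r - t has small norm on true triples (the planted translational
#' structure) while corrupted triples score like random pairs.
#'
#' @param kg A \linkS4class{HeteroKG}.
#' @param dim Embedding dimension (>= 2).
#' @param mode \code{"translational"} (default) or \code{"random"}.
#' @param rngSeed Integer seed.
#' @return An \linkS4class{EmbeddingStore} covering all entities, all
#'   relation types, and \code{"self"}.
#' @export
genEmbeddings <- function(kg, dim = 32L, mode = c("translational", "random"),
                          rngSeed = 1L) {
  mode <- match.arg(mode)
  stopifnot(dim >= 2L)
  set.seed(deriveSeed(rngSeed, 404L))
  ents <- sort(unique(c(kg@nodes$id, kg@triples$head, kg@triples$tail)))
  rels <- sort(unique(c(kg@triples$relation, "self")))
  E <- matrix(stats::rnorm(length(ents) * dim, sd = 1 / sqrt(dim)),
              ncol = dim, dimnames = list(ents))
  R <- matrix(stats::rnorm(length(rels) * dim, sd = 1 / sqrt(dim)),
              ncol = dim, dimnames = list(rels))
  if (mode == "translational") {
    pinned <- stats::setNames(rep(FALSE, length(ents)), ents)
    for (i in seq_len(nrow(kg@triples))) {
      h <- kg@triples$head[i]
      t <- kg@triples$tail[i]
      r <- kg@triples$relation[i]
      if (!pinned[t] && t != h) {
        E[t, ] <- E[h, ] + R[r, ] + stats::rnorm(dim, sd = 0.02 / sqrt(dim))
        pinned[t] <- TRUE
      }
      pinned[h] <- TRUE
    }
  }
  methods::new("EmbeddingStore", vectors = rbind(E, R))
}

#' Write a full synthetic dataset to disk
#'
#' Emits the four pipeline inputs in their external formats (drug table
#' CSV, DDI CSV, triple TSV, embedding text) plus the planted truth and
#' the resolved spec as JSON/YAML, making synthetic and real runs
#' path-identical.
#'
#' @param spec A \code{\link{syntheticSpec}}.
#' @param dir Output directory (created if needed).
#' @param nPairs DDI rows to emit (see \code{\link{genDdi}}).
#' @return Invisibly, the list of generated objects.
#' @export
writeSyntheticDataset <- function(spec = syntheticSpec(), dir,
                                  nPairs = 200L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  kg <- genKg(spec)
  nAll <- spec$nDrugs + spec$nUnreachable
  ids <- c(.drugIds(spec$nDrugs),
           if (spec$nUnreachable > 0L)
             sprintf("Compound::DU%02d", seq_len(spec$nUnreachable)))
  drugs <- genSmiles(nAll, rngSeed = spec$seed, ids = ids)
  ddi <- genDdi(kg, spec, nPairs = nPairs)
  store <- genEmbeddings(kg, dim = spec$embDim, rngSeed = spec$seed)
  writeTable(drugs, file.path(dir, "drugs.csv"))
  writeTable(ddi, file.path(dir, "ddi.csv"))
  writeTriples(kg, file.path(dir, "kg_triples.tsv"))
  writeEmbeddings(store, file.path(dir, "embeddings.txt"))
  jsonlite::write_json(attr(kg, "truth"), file.path(dir, "truth.json"),
                       pretty = TRUE)
  yaml::write_yaml(unclass(spec), file.path(dir, "synthetic_spec.yaml"))
  invisible(list(kg = kg, drugs = drugs, ddi = ddi, store = store))
}
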