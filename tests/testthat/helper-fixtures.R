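# Shared fixtures built in code: tiny configs, hand-made KGs and
# anchor-centred screening scenarios.

# central finite differences for gradient checks
numericalGrad <- function(fwd, param, eps = 1e-6) {
  g <- param$value * 0
  for (i in seq_along(param$value)) {
    v0 <- param$value[i]
    param$value[i] <- v0 + eps
    adTapeBegin(); up <- as.numeric(fwd()$value); adTapeEnd()
    param$value[i] <- v0 - eps
    adTapeBegin(); dn <- as.numeric(fwd()$value); adTapeEnd()
    param$value[i] <- v0
    g[i] <- (up - dn) / (2 * eps)
  }
  g
}

# desk-scale model config used by most neural tests
tinyConfig <- function(...) {
  defaults <- list(L = 48L, dEmb = 16L, dModel = 16L, nLayers = 1L,
                   nHead = 2L, dFf = 32L, kHeads = 2L, dPrime = 8L,
                   dKg = 8L, convChannels = 16L, headHidden = c(32L, 16L),
                   walkSteps = 50L, walkIterations = 30L,
                   walkSpread = 500L, maxEpochs = 5L, seed = 1L)
  override <- list(...)
  do.call(runConfig, utils::modifyList(defaults, override))
}

# KG from an edge list given as "Family::id" strings
kgFromEdges <- function(heads, tails, relation = "rel") {
  heteroKG(data.frame(head = heads, relation = relation, tail = tails,
                      stringsAsFactors = FALSE))
}

# chain Drug - g1 - ... - g(nHops-1) - Pathway (drug at nHops from pathway)
chainKg <- function(nHops, drug = "Compound::D001") {
  stopifnot(nHops >= 1)
  nodes <- c(drug, sprintf("Gene::gc%02d", seq_len(nHops - 1)),
             "Pathway::PX")
  kgFromEdges(nodes[-length(nodes)], nodes[-1])
}

# Deterministic drug-centred neighborhood: nodes within `radius` hops of
# the drug, emulating on a desk-scale KG the locality that budget-limited
# random walks produce on a large one; the pathway-anchored extraction is
# then applied unchanged.
egoSubgraph <- function(kg, drug, radius = 3L, hopLimit = 4L) {
  g <- igraph::graph_from_data_frame(kg@triples[, c("head", "tail")],
                                     directed = FALSE,
                                     vertices = kg@nodes$id)
  keep <- names(which(igraph::distances(g, v = drug)[1, ] <= radius))
  nb <- heteroKG(kg@triples[kg@triples$head %in% keep &
                            kg@triples$tail %in% keep, , drop = FALSE],
                 nodes = kg@nodes[kg@nodes$id %in% keep, , drop = FALSE])
  pathwayAnchoredExtract(nb, drug, hopLimit)
}

# Small trained-pipeline fixture: generated dataset, filtered tables,
# vocabulary and precomputed per-drug inputs.
miniTrainingSetup <- function(seed = 21, nDrugs = 8, nPairs = 24) {
  cfg <- tinyConfig(seed = seed, maxEpochs = 4L, dropout = 0)
  spec <- syntheticSpec(nDrugs = nDrugs, mediatorDensity = 0.4,
                        nClasses = 3, seed = seed)
  kg <- genKg(spec)
  drugs <- genSmiles(nDrugs, rngSeed = seed)
  ddi <- genDdi(kg, spec, nPairs = nPairs)
  store <- genEmbeddings(kg, dim = 16, rngSeed = seed)
  subs <- drugSubgraphs(kg, drugs, cfg)
  filt <- consistencyFilter(drugs, ddi, subs)
  vocab <- buildVocab(filt$drugs$smiles)
  preps <- prepareDrugInputs(filt$drugs, vocab, cfg, subs, store)
  list(cfg = cfg, ddi = filt$ddis, drugs = filt$drugs, vocab = vocab,
       preps = preps, subs = subs, store = store)
}

# Anchor-centred screening scenario. Partners are wired through the
# candidate pathway "Pathway::PSTAR" (anchor - gene - PSTAR - gene -
# partner) when bridged; every drug also has a private gene + pathway.
# Returns ddi table, subgraphs (pathway-anchored) and the planted pathway.
anchorScenario <- function(seed, nInter = 5L, nNon = 5L,
                           shuffleLabels = FALSE) {
  set.seed(seed)
  anchor <- "Compound::ANCH"
  partners <- sprintf("Compound::PART%02d", seq_len(nInter + nNon))
  bridged <- partners[seq_len(nInter)]
  heads <- c(); tails <- c(); rels <- c()
  add <- function(h, t, r = "rel") {
    heads <<- c(heads, h); tails <<- c(tails, t); rels <<- c(rels, r)
  }
  for (d in c(anchor, partners)) {
    tag <- sub("^Compound::", "", d)
    g <- paste0("Gene::priv_", tag)
    p <- paste0("Pathway::priv_", tag)
    add(d, g, "compound_gene"); add(g, p, "gene_pathway")
    # variable decoy attachments: realistic per-drug subgraph size jitter
    nDecoy <- sample(1:3, 1)
    for (k in seq_len(nDecoy)) {
      dg <- sprintf("Gene::decoy_%s_%d", tag, k)
      add(d, dg, "compound_gene")
      if (runif(1) < 0.5)
        add(dg, sprintf("Disease::dis_%s_%d", tag, k), "gene_disease")
    }
  }
  gA <- "Gene::bridgeA"
  add(anchor, gA, "compound_gene"); add(gA, "Pathway::PSTAR", "gene_pathway")
  for (d in bridged) {
    gB <- paste0("Gene::bridgeB_", sub("^Compound::", "", d))
    add("Pathway::PSTAR", gB, "pathway_gene"); add(gB, d, "gene_compound")
  }
  kg <- heteroKG(data.frame(head = heads, relation = rels, tail = tails,
                            stringsAsFactors = FALSE))
  interacting <- if (shuffleLabels) {
    set.seed(seed)
    sample(partners, nInter)
  } else bridged
  ddi <- data.frame(drug_a = anchor, drug_b = interacting, label = 1L,
                    stringsAsFactors = FALSE)
  subs <- lapply(c(anchor, partners), function(d) egoSubgraph(kg, d))
  names(subs) <- c(anchor, partners)
  list(anchor = anchor, ddi = ddi, subgraphs = subs,
       pathway = "Pathway::PSTAR")
}
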