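test_that("family filtering keeps edges only when both endpoints survive", {
  kg <- kgFromEdges(
    c("Compound::c", "Compound::c", "Gene::g", "Compound::c"),
    c("Gene::g", "Side-effect::s", "Atc::other", "Disease::d"))
  cgpds <- filterFamilies(kg, "CGPDS")
  cgpd <- filterFamilies(kg, "CGPD")
  expect_equal(edgeCount(cgpds), 3L)   # Gene-Other edge dropped
  expect_equal(edgeCount(cgpd), 2L)    # Compound-SideEffect also dropped
  expect_false("Side-effect::s" %in% cgpd@nodes$id)
  # surviving nodes are retained even when isolated
  expect_true("Gene::g" %in% cgpd@nodes$id)
  expect_error(filterFamilies(kg, "XYZ"))
})

test_that("CGPD counts never exceed CGPDS counts", {
  for (seed in 1:3) {
    kg <- genKg(syntheticSpec(nDrugs = 10, seed = seed))
    a <- stageCounts(filterFamilies(kg, "CGPDS"))
    b <- stageCounts(filterFamilies(kg, "CGPD"))
    expect_true(all(b <= a))
  }
})

test_that("self-loops attach exactly to edge-less drugs", {
  kg <- heteroKG(
    data.frame(head = "Compound::a", relation = "r", tail = "Gene::g"),
    nodes = data.frame(id = c("Compound::a", "Compound::b", "Gene::g"),
                       family = c("Compound", "Compound", "Gene")))
  out <- attachSelfLoops(kg, c("Compound::a", "Compound::b"))
  expect_equal(edgeCount(out), 2L)
  loop <- out@triples[out@triples$relation == "self", ]
  expect_identical(loop$head, "Compound::b")
  expect_identical(loop$tail, "Compound::b")
  # empty drug set: identity
  expect_identical(attachSelfLoops(kg, character(0))@triples, kg@triples)
})

test_that("random walk respects degenerate parameters and reachability", {
  # seed with only a self-loop is absorbing
  kg <- attachSelfLoops(
    heteroKG(data.frame(head = "Gene::g", relation = "r",
                        tail = "Pathway::p"),
             nodes = data.frame(id = c("Compound::a", "Gene::g",
                                       "Pathway::p"),
                                family = c("Compound", "Gene", "Pathway"))),
    "Compound::a")
  nb <- randomWalkNeighborhood(kg, "Compound::a", rngSeed = 1)
  expect_identical(nb@nodes$id, "Compound::a")
  expect_equal(edgeCount(nb), 1L)  # the self-loop
  # restart probability 1 never leaves the seed
  chain <- chainKg(3)
  nb1 <- randomWalkNeighborhood(chain, "Compound::D001", restartProb = 1,
                                rngSeed = 1)
  expect_identical(nb1@nodes$id, "Compound::D001")
  # generous budgets reach the full 3-node path
  p3 <- kgFromEdges(c("Pathway::p", "Gene::g"),
                    c("Gene::g", "Compound::c"))
  nb3 <- randomWalkNeighborhood(p3, "Compound::c", steps = 50,
                                iterations = 20, rngSeed = 1)
  expect_setequal(nb3@nodes$id, c("Pathway::p", "Gene::g", "Compound::c"))
  expect_error(randomWalkNeighborhood(p3, "Compound::zz"), "not in KG")
})

test_that("walks are deterministic and monotone in their budgets", {
  kg <- filterFamilies(genKg(syntheticSpec(nDrugs = 12, seed = 4)), "CGPDS")
  kg <- attachSelfLoops(kg, "Compound::D001")
  full <- randomWalkNeighborhood(kg, "Compound::D001", steps = 40,
                                 iterations = 20, rngSeed = 9)
  again <- randomWalkNeighborhood(kg, "Compound::D001", steps = 40,
                                  iterations = 20, rngSeed = 9)
  expect_identical(full@nodes$id, again@nodes$id)
  # halved budgets visit a subset of the full-budget neighborhood
  half <- randomWalkNeighborhood(kg, "Compound::D001", steps = 20,
                                 iterations = 10, rngSeed = 9)
  expect_true(all(half@nodes$id %in% full@nodes$id))
})

test_that("pathway anchoring keeps exactly the 4-hop-reachable structure", {
  # 4-hop chain: drug retained at the limit
  nb4 <- chainKg(4)
  sg4 <- pathwayAnchoredExtract(nb4, "Compound::D001", hopLimit = 4)
  expect_false(sg4@unreachable)
  expect_equal(anchorDistance(sg4), 4)
  # 5-hop chain: flagged unreachable, not an error
  nb5 <- chainKg(5)
  sg5 <- pathwayAnchoredExtract(nb5, "Compound::D001", hopLimit = 4)
  expect_true(sg5@unreachable)
  # star around a pathway: all leaves retained at distance 1
  star <- kgFromEdges(rep("Pathway::hub", 6),
                      c(sprintf("Gene::l%d", 1:5), "Compound::D001"))
  sgs <- pathwayAnchoredExtract(star, "Compound::D001")
  expect_equal(nodeCount(sgs), 7L)
  expect_identical(sgs@anchors, "Pathway::hub")
})

test_that("consistency filter drops flagged drugs and their DDI rows", {
  spec <- syntheticSpec(nDrugs = 4, nUnreachable = 1, mediatorDensity = 0.5,
                        seed = 6)
  kg <- genKg(spec)
  ids <- c(sprintf("Compound::D%03d", 1:4), "Compound::DU01")
  drugs <- genSmiles(5, rngSeed = 6, ids = ids)
  ddi <- data.frame(drug_a = ids[c(1, 1, 2, 5)],
                    drug_b = ids[c(2, 5, 3, 3)],
                    label = c(1L, 1L, 0L, 2L))
  subs <- drugSubgraphs(kg, drugs, tinyConfig())
  filt <- consistencyFilter(drugs, ddi, subs)
  expect_identical(filt$removals$drug_id, "Compound::DU01")
  expect_match(filt$removals$reason, "no pathway reachable")
  expect_equal(nrow(filt$drugs), 4L)
  expect_equal(nrow(filt$ddis), 2L)  # the two rows touching DU01 dropped
  # no removals: identity
  filt2 <- consistencyFilter(filt$drugs, filt$ddis, subs)
  expect_identical(filt2$drugs, filt$drugs)
  expect_equal(nrow(filt2$removals), 0L)
})

test_that("stage counts report exact node/edge totals", {
  tri <- kgFromEdges(c("Gene::a", "Gene::b", "Gene::c"),
                     c("Gene::b", "Gene::c", "Gene::a"))
  expect_equal(stageCounts(tri), c(nodes = 3L, edges = 3L))
  less <- heteroKG(tri@triples[-1, ], nodes = tri@nodes)
  expect_equal(stageCounts(less), c(nodes = 3L, edges = 2L))
  empty <- heteroKG(tri@triples[0, ],
                    nodes = tri@nodes[0, ])
  expect_equal(stageCounts(empty), c(nodes = 0L, edges = 0L))
})

test_that("every retained drug reaches an anchor within the hop limit (BFS audit)", {
  cfg <- tinyConfig()
  spec <- syntheticSpec(nDrugs = 15, mediatorDensity = 0.3, seed = 8)
  kg <- genKg(spec)
  drugs <- genSmiles(15, rngSeed = 8)
  subs <- drugSubgraphs(kg, drugs, cfg)
  for (d in names(subs)) {
    if (subs[[d]]@unreachable) next
    expect_lte(anchorDistance(subs[[d]]), cfg$hopLimit)
  }
})
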