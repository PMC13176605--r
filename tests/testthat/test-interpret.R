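mkSub <- function(drug, edges) {
  ids <- unique(c(drug, edges$head, edges$tail))
  new("DrugSubgraph", drug = drug, entities = sort(ids),
      relations = sort(unique(edges$relation)),
      anchors = sort(ids[entityFamily(ids) == "Pathway"]),
      triples = edges, unreachable = FALSE)
}

edges <- function(h, t, r = "rel") data.frame(head = h, relation = r,
                                              tail = t,
                                              stringsAsFactors = FALSE)

test_that("merging marks shared pathways and the bridge flag correctly", {
  a <- mkSub("Compound::A", edges(c("Compound::A", "Gene::ga"),
                                  c("Gene::ga", "Pathway::P1")))
  b <- mkSub("Compound::B", edges(c("Compound::B", "Gene::gb"),
                                  c("Gene::gb", "Pathway::P2")))
  m <- mergeSubgraphs(a, b)
  expect_false(m@connectedThroughPathway)
  expect_length(m@sharedPathways, 0L)
  # now share P1
  b2 <- mkSub("Compound::B", edges(c("Compound::B", "Gene::gb"),
                                   c("Gene::gb", "Pathway::P1")))
  m2 <- mergeSubgraphs(a, b2)
  expect_identical(m2@sharedPathways, "Pathway::P1")
  expect_true(m2@connectedThroughPathway)
  expect_identical(m2@nodes$color[m2@nodes$id == "Pathway::P1"], "shared")
  expect_identical(m2@nodes$color[m2@nodes$id == "Gene::ga"], "a")
  # self-merge: everything shared
  ms <- mergeSubgraphs(a, a)
  expect_true(all(ms@nodes$color == "shared"))
  expect_equal(stageCounts(ms), stageCounts(a))
})

test_that("centralities match closed forms on canonical graphs", {
  # path a-b-c
  p <- nodeCentralities(edges(c("Gene::a", "Gene::b"),
                              c("Gene::b", "Gene::c")))
  expect_equal(p$betweenness[p$node == "Gene::b"], 1)
  expect_equal(p$betweenness[p$node == "Gene::a"], 0)
  expect_equal(p$closeness[p$node == "Gene::b"], 1)
  expect_equal(p$closeness[p$node == "Gene::a"], (1 + 1 / 2) / 2)
  # star: center degree 1 after normalization by n - 1
  st <- nodeCentralities(edges(rep("Gene::hub", 5),
                               sprintf("Gene::l%d", 1:5)))
  expect_equal(st$degree[st$node == "Gene::hub"], 1)
  expect_equal(st$degree[st$node == "Gene::l1"], 0.2)
  # cycle: all nodes identical on all four measures
  cy <- nodeCentralities(edges(sprintf("Gene::c%d", 1:5),
                               sprintf("Gene::c%d", c(2:5, 1))))
  for (col in c("degree", "betweenness", "closeness", "eigenvector"))
    expect_equal(diff(range(cy[[col]])), 0, tolerance = 1e-10)
  # eigenvector is scaled to max 1 per component
  expect_equal(max(cy$eigenvector), 1, tolerance = 1e-8)
  expect_equal(st$eigenvector[st$node == "Gene::hub"], 1, tolerance = 1e-8)
  expect_error(nodeCentralities(data.frame(head = character(0),
                                           relation = character(0),
                                           tail = character(0))),
               "empty graph")
  expect_error(nodeCentralities(edges("Gene::a", "Gene::b"), "Gene::zz"),
               "not in graph")
})

test_that("Cliff's delta captures dominance and sign", {
  expect_equal(cliffsDelta(c(5, 6, 7), c(1, 2, 3)), 1)
  expect_equal(cliffsDelta(c(1, 2, 3), c(5, 6, 7)), -1)
  expect_equal(cliffsDelta(c(1, 2), c(1, 2)), 0)
  expect_true(is.na(cliffsDelta(numeric(0), 1:3)))
})

test_that("weighted separation applies the fixed centrality weights", {
  expect_equal(weightedSeparation(c(1, 1, 1, 1)), 1)
  expect_equal(weightedSeparation(c(1, 0, 0, 0)), 0.4)
  expect_equal(weightedSeparation(c(0, 1, 0, 0)), 0.3)
  expect_equal(weightedSeparation(c(0, 0, 0, 0)), 0)
  expect_equal(weightedSeparation(c(1, 1, 1, 1), coverage = 0.5), 0.5)
  expect_equal(weightedSeparation(c(0, 1, 0, 0), eigenvectorBonus = 1), 0.6)
  expect_equal(sum(repWeights()), 1)
})

test_that("partner-group distributions count covering partners", {
  sc <- anchorScenario(seed = 101, nInter = 3, nNon = 3)
  rec <- partnerGroupDistributions(sc$anchor, 1L, sc$ddi, sc$subgraphs,
                                   pathway = sc$pathway)
  expect_setequal(unique(rec$group), c("interacting", "noninteracting"))
  covered <- rec[rec$covered, ]
  expect_true(all(is.finite(covered$betweenness)))
  # interacting partners all cover the planted pathway
  expect_true(all(rec$covered[rec$group == "interacting"]))
  # degenerate: label with no interacting partners
  expect_error(partnerGroupDistributions(sc$anchor, 99L, sc$ddi,
                                         sc$subgraphs),
               "interacting")
})

test_that("screening keeps the planted bridge and ranks it first", {
  sc <- anchorScenario(seed = 202, nInter = 5, nNon = 5)
  rec <- partnerGroupDistributions(sc$anchor, 1L, sc$ddi, sc$subgraphs)
  scr <- screenPathways(rec)
  expect_gt(nrow(scr), 0)
  expect_identical(scr$pathway[1], sc$pathway)
  expect_true(scr$passed[1])
  # BH with a single hypothesis family member per centrality: q >= p
  expect_true(all(scr$betweenness_q >= scr$betweenness_p - 1e-15))
})

test_that("single-hypothesis BH leaves the p-value untouched", {
  expect_equal(stats::p.adjust(0.031, method = "BH"), 0.031)
})

test_that("screening ties break lexicographically by pathway ID", {
  # two identical pathways by construction: symmetric records
  rec <- do.call(rbind, lapply(c("Pathway::B", "Pathway::A"), function(pw) {
    data.frame(partner = sprintf("p%d", 1:8),
               group = rep(c("interacting", "noninteracting"), each = 4),
               pathway = pw, covered = TRUE,
               degree = c(5, 6, 7, 8, 1, 2, 3, 4) / 10,
               betweenness = c(5, 6, 7, 8, 1, 2, 3, 4) / 10,
               closeness = c(5, 6, 7, 8, 1, 2, 3, 4) / 10,
               eigenvector = c(5, 6, 7, 8, 1, 2, 3, 4) / 10)
  }))
  scr <- screenPathways(rec, alpha = 0.2)
  expect_identical(scr$pathway, c("Pathway::A", "Pathway::B"))
  expect_equal(scr$score[1], scr$score[2])
})

test_that("too-small groups are skipped with a note, not tested", {
  rec <- data.frame(partner = c("p1", "p2", "p3"),
                    group = c("interacting", "noninteracting",
                              "noninteracting"),
                    pathway = "Pathway::X", covered = TRUE,
                    degree = 1:3 / 3, betweenness = 1:3 / 3,
                    closeness = 1:3 / 3, eigenvector = 1:3 / 3)
  scr <- screenPathways(rec, coverageMin = 0)
  expect_equal(nrow(scr), 0L)
  expect_identical(attr(scr, "skipped"), "Pathway::X")
})

test_that("distribution summaries mark the pooled 95th percentile", {
  s <- distributionSummary(1:50, 51:100)
  # type-7 quantile of 1..100 at 0.95 sits between 95 and 96
  expect_gte(s$threshold, 95)
  expect_lte(s$threshold, 96)
  expect_setequal(s$rug, 96:100)
  # identical groups: zero mean difference
  s2 <- distributionSummary(c(1, 2, 3), c(1, 2, 3))
  expect_equal(s2$meanDiff, 0)
  # minimal two-point groups work
  s3 <- distributionSummary(c(1, 2), c(3, 4))
  expect_false(s3$fallback)
  # constant sample falls back to a histogram summary with a warning
  expect_warning(s4 <- distributionSummary(c(2, 2, 2), c(1, 3, 5)),
                 "constant")
  expect_true(s4$fallback)
  expect_error(distributionSummary(1, 1:3), ">= 2 points")
  # plot file is produced
  f <- withr::local_tempfile(fileext = ".png")
  plotDistributionSummary(s, f)
  expect_true(file.exists(f) && file.size(f) > 0)
})
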