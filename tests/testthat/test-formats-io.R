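test_that("triple files parse in order and reject malformed lines", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Compound::a\tbinds\tGene::b",
               "Gene::b\tmember\tPathway::p",
               "Compound::a\ttreats\tDisease::d"), f)
  kg <- readTriples(f)
  expect_equal(edgeCount(kg), 3L)
  expect_identical(kg@triples$relation, c("binds", "member", "treats"))
  expect_setequal(kg@nodes$family[match(c("Compound::a", "Pathway::p"),
                                        kg@nodes$id)],
                  c("Compound", "Pathway"))
  writeLines(character(0), f)
  expect_equal(edgeCount(readTriples(f)), 0L)
  writeLines(c("a\tb"), f)
  expect_error(readTriples(f), "line.*1")
  expect_error(readTriples("no/such/file.tsv"), "not found")
})

test_that("triple round-trip preserves records exactly", {
  f <- withr::local_tempfile(fileext = ".tsv")
  kg <- genKg(syntheticSpec(nDrugs = 5, seed = 3))
  writeTriples(kg, f)
  expect_identical(readTriples(f)@triples, kg@triples)
})

test_that("drug and DDI tables validate and round-trip with both delimiters", {
  drugs <- data.frame(drug_id = c("Compound::D001", "Compound::D002"),
                      smiles = c("CCO", "c1ccccc1"))
  ddi <- data.frame(drug_a = "Compound::D001", drug_b = "Compound::D002",
                    label = 3L)
  for (ext in c(".csv", ".tsv")) {
    fd <- withr::local_tempfile(fileext = ext)
    fi <- withr::local_tempfile(fileext = ext)
    writeTable(drugs, fd); writeTable(ddi, fi)
    expect_identical(readDrugTable(fd), drugs)
    expect_identical(readDdiTable(fi, drugs), ddi)
  }
})

test_that("table invariants are enforced", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeTable(data.frame(drug_id = c("a", "a"), smiles = c("C", "N")), f)
  expect_error(readDrugTable(f), "duplicate")
  writeTable(data.frame(drug_id = "a", smiles = "  "), f)
  expect_error(readDrugTable(f), "empty SMILES")
  writeTable(data.frame(drug_a = "a", drug_b = "b", label = 1.5), f)
  expect_error(readDdiTable(f), "integers")
  writeTable(data.frame(drug_a = "a", drug_b = "zz", label = 1L), f)
  expect_error(readDdiTable(f, data.frame(drug_id = c("a", "b"),
                                          smiles = "C")), "unknown drug")
})

test_that("embedding stores read strictly and look up strictly", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(paste(c("Compound::x", format(seq_len(400) / 400)),
                   collapse = " "), f)
  st <- readEmbeddings(f)
  expect_equal(dim(st@vectors), c(1L, 400L))
  expect_equal(embeddingDim(st), 400L)
  # unknown identifier is a detectable error, not a silent zero
  expect_error(embeddingLookup(st, "Compound::y"), "Compound::y")
  writeLines(c("a 1 2 3", "b 1 2"), f)
  expect_error(readEmbeddings(f), "ragged")
})

test_that("embedding round-trip reproduces values", {
  kg <- genKg(syntheticSpec(nDrugs = 4, seed = 5))
  st <- genEmbeddings(kg, dim = 8, rngSeed = 5)
  f <- withr::local_tempfile(fileext = ".txt")
  writeEmbeddings(st, f)
  st2 <- readEmbeddings(f)
  expect_identical(rownames(st2@vectors), rownames(st@vectors))
  expect_equal(st2@vectors, st@vectors, tolerance = 1e-12)
})

test_that("subgraph JSON round-trips", {
  cfg <- tinyConfig()
  kg <- genKg(syntheticSpec(nDrugs = 6, seed = 2))
  drugs <- genSmiles(6, rngSeed = 2)
  subs <- drugSubgraphs(kg, drugs, cfg)
  sg <- subs[[1]]
  f <- withr::local_tempfile(fileext = ".json")
  writeSubgraph(sg, f)
  back <- readSubgraph(f)
  expect_identical(back@drug, sg@drug)
  expect_identical(back@entities, sg@entities)
  expect_identical(back@relations, sg@relations)
  expect_identical(back@anchors, sg@anchors)
  expect_equal(back@triples, sg@triples, ignore_attr = TRUE)
})

test_that("run configuration serializes losslessly and rejects unknowns", {
  cfg <- runConfig(dKg = 12L, walkRestart = 0.25, variant = "CGPD",
                   headHidden = c(64L, 32L))
  f <- withr::local_tempfile(fileext = ".yaml")
  saveConfig(cfg, f)
  expect_identical(loadConfig(f), cfg)
  writeLines("bogusField: 1", f)
  expect_error(loadConfig(f), "unknown config field")
  expect_error(runConfig(variant = "XYZ"))
  expect_error(runConfig(dModel = 10, nHead = 4))
})
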