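test_that("pair-feature width follows D = 2(dModel + K dPrime + dKg)", {
  expect_equal(pairFeatureDim(runConfig()), 424L)  # 2(128 + 64 + 20)
  expect_equal(pairFeatureDim(runConfig(dModel = 64L, kHeads = 2L,
                                        dPrime = 8L, dKg = 10L)), 180L)
  expect_equal(pairFeatureDim(tinyConfig()), 80L)  # 2(16 + 16 + 8)
  # ablation variants restrict the blocks
  expect_equal(pairFeatureDim(runConfig(ablation = "transformer")), 256L)
  expect_equal(pairFeatureDim(runConfig(ablation = "kg-rw")), 40L)
  expect_error(ablationBlocks("bogus"), "unknown ablation variant")
})

test_that("fusion concatenates in fixed order and is order-sensitive", {
  a <- list(trans = c(1, 2), gat = c(3), kg = c(4, 5))
  b <- list(trans = c(6, 7), gat = c(8), kg = c(9, 10))
  expect_equal(fusePair(a, b), c(1:5, 6:10))
  expect_equal(fusePair(b, a), c(6:10, 1:5))
  expect_equal(fusePair(a, b, ablationBlocks("transformer+gat")),
               c(1, 2, 3, 6, 7, 8))
  z <- list(trans = c(0, 0), gat = 0, kg = c(0, 0))
  expect_equal(fusePair(z, z), rep(0, 10))
})

test_that("the head emits proper probabilities", {
  set.seed(3)
  head <- headInit(6, C = 4, hidden = c(8L), dropout = 0.3)
  X <- matrix(rnorm(30), 5, 6)
  adTapeBegin()
  p <- softmaxProbs(headForward(head, X, training = FALSE))
  adTapeEnd()
  expect_true(all(p >= 0))
  expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-6)
  # two-logit softmax at (0, 0) is (0.5, 0.5)
  expect_equal(softmaxProbs(matrix(0, 1, 2)), matrix(0.5, 1, 2))
})

test_that("pair-stratified folds preserve class counts within one", {
  ddi <- data.frame(drug_a = sprintf("d%03d", 1:100),
                    drug_b = sprintf("e%03d", 1:100),
                    label = rep(0:4, each = 20))
  plan <- makeFolds(ddi, k = 5, mode = "pair", rngSeed = 2)
  expect_setequal(unique(plan$fold), 1:5)
  counts <- table(plan$fold, ddi$label)
  expect_true(all(counts == 4))  # 20 per class / 5 folds exactly
  # every pair appears in exactly one test fold
  expect_equal(sort(unlist(lapply(1:5, function(f)
    foldSplit(ddi, plan, f)$test))), 1:100)
  # determinism
  plan2 <- makeFolds(ddi, k = 5, mode = "pair", rngSeed = 2)
  expect_identical(plan2$fold, plan$fold)
  # rare classes pool into a reported remainder stratum
  ddi$label[1:3] <- 9L
  plan3 <- makeFolds(ddi, k = 5, mode = "pair", rngSeed = 2)
  expect_equal(plan3$remainderClasses, 9L)
  expect_error(makeFolds(ddi, k = 1), "k must be >= 2")
})

test_that("drug-disjoint folds certify zero drug overlap", {
  set.seed(4)
  drugs <- sprintf("d%02d", 1:10)
  pairs <- t(combn(drugs, 2))
  ddi <- data.frame(drug_a = pairs[, 1], drug_b = pairs[, 2],
                    label = rbinom(nrow(pairs), 1, 0.5))
  plan <- makeFolds(ddi, k = 3, mode = "drug-disjoint", rngSeed = 5)
  for (f in 1:3) {
    sp <- foldSplit(ddi, plan, f)
    expect_length(sp$sharedDrugs, 0L)
    # every test pair has both drugs in the holdout group
    expect_true(all(plan$drugGroup[ddi$drug_a[sp$test]] == f))
    expect_true(all(plan$drugGroup[ddi$drug_b[sp$test]] == f))
  }
})

test_that("early stopping halts after the configured patience and keeps the best epoch", {
  tr <- earlyStopTrace(c(0.5, 0.6, rep(0.6, 11)), patience = 10)
  expect_equal(tr$stopEpoch, 12L)
  expect_equal(tr$bestEpoch, 2L)
  # strictly improving: no stop
  tr2 <- earlyStopTrace(seq(0.1, 0.9, length.out = 30), patience = 10)
  expect_equal(tr2$stopEpoch, 30L)
  expect_equal(tr2$bestEpoch, 30L)
  # plateau from the start
  tr3 <- earlyStopTrace(rep(0.5, 20), patience = 5)
  expect_equal(tr3$stopEpoch, 6L)
  expect_equal(tr3$bestEpoch, 1L)
})

test_that("training is reproducible under a fixed seed and logs CSV history", {
  s <- miniTrainingSetup()
  run <- function() {
    model <- createModel(s$cfg, s$vocab, C = 3)
    f <- withr::local_tempfile(fileext = ".csv")
    fit <- trainFold(model, s$preps, s$ddi[1:16, ], s$ddi[17:20, ],
                     s$cfg, historyCsv = f)
    list(hist = fit$history, csv = read.csv(f))
  }
  r1 <- run(); r2 <- run()
  # numerically reproducible (threaded BLAS may jitter in the last bits)
  expect_equal(r1$hist, r2$hist, tolerance = 1e-10)
  # CSV stores ~15 significant digits
  expect_equal(r1$csv$train_loss, r1$hist$train_loss, tolerance = 1e-12)
  expect_named(r1$csv, c("epoch", "train_loss", "train_acc", "val_acc"))
  model <- createModel(s$cfg, s$vocab, C = 3)
  expect_error(trainFold(model, s$preps, s$ddi[0, ], s$ddi, s$cfg),
               "empty training set")
})

test_that("metric reports match hand-computed confusion-matrix values", {
  # confusion [[8, 2], [3, 7]]
  truth <- c(rep(0, 10), rep(1, 10))
  pred <- c(rep(0, 8), rep(1, 2), rep(0, 3), rep(1, 7))
  r <- metricReport(truth, pred)
  expect_equal(r$accuracy, 0.75)
  expect_equal(r$perClass$precision, c(8 / 11, 7 / 9))
  expect_equal(r$perClass$recall, c(0.8, 0.7))
  # perfect predictions
  rp <- metricReport(0:3, 0:3)
  expect_equal(rp$accuracy, 1)
  expect_true(all(rp$perClass$f1 == 1))
  # single-class truth: absent-class handling is flagged, not silent
  rs <- metricReport(rep(1, 5), c(1, 1, 1, 1, 0), C = 2)
  expect_true(0 %in% rs$zeroDivision)
  expect_equal(rs$macro[["recall"]], 0.8)  # only the present class averaged
  expect_error(metricReport(integer(0), integer(0)), "empty test set")
})

test_that("binary AUCs match the reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(11)
  truth <- rbinom(60, 1, 0.5)
  score <- runif(60) + 0.4 * truth
  probs <- cbind(1 - score, score)
  r <- metricReport(truth, as.integer(score > 0.5), probs = probs, C = 2)
  ref <- as.numeric(suppressMessages(pROC::auc(truth, score)))
  expect_equal(r$rocAuc, ref, tolerance = 1e-12)
  expect_true(r$prAuc > 0 && r$prAuc <= 1)
})

test_that("cross-validation keeps KG inputs frozen and certifies splits", {
  s <- miniTrainingSetup(seed = 31)
  cfg <- s$cfg
  cfg$folds <- 3L
  cfg$maxEpochs <- 2L
  cv <- crossValidate(s$drugs, s$ddi, s$vocab, cfg,
                      subgraphs = s$subs, store = s$store)
  expect_true(cv$frozenFeatureCheck)
  done <- !vapply(cv$folds, is.null, TRUE)
  expect_true(any(done))
  for (f in cv$folds[done]) {
    expect_true(f$accuracy >= 0 && f$accuracy <= 1)
  }
})

test_that("ablation variants train with restricted fusion blocks", {
  s <- miniTrainingSetup(seed = 41)
  cfg <- s$cfg
  cfg$folds <- 2L
  cfg$maxEpochs <- 2L
  for (variant in c("transformer", "kg-rw+sp")) {
    cv <- runAblation(variant, s$drugs, s$ddi, s$vocab, cfg,
                      subgraphs = s$subs, store = s$store)
    done <- which(!vapply(cv$folds, is.null, TRUE))
    expect_true(length(done) > 0, info = variant)
  }
})
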