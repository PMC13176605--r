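## Cross-validation planning, training with early stopping and
## checkpointing, and metric reporting.

#' Build a cross-validation fold plan
#'
#' Pair-stratified mode shuffles each class and deals its pairs
#' round-robin, so per-fold class counts differ from the ideal by at most
#' one; classes with fewer than k members are pooled into a reported
#' remainder stratum (their labels are untouched). Drug-disjoint mode
#' partitions the drugs into k groups; fold i tests on pairs with both
#' drugs in group i and trains on pairs with both drugs outside it, so
#' train and test share no drugs by construction.
#'
#' @param ddiTable DDI table (drug_a, drug_b, label).
#' @param k Fold count (>= 2).
#' @param mode \code{"pair"} or \code{"drug-disjoint"}.
#' @param rngSeed Integer seed.
#' @return List with \code{fold} (per-pair test-fold index; NA for pairs
#'   unusable in any fold under drug-disjoint mode is never needed --
#'   every pair gets the fold of its drugs' groups or 0 when its drugs'
#'   groups differ), \code{mode}, \code{k}, \code{remainderClasses}, and
#'   for drug-disjoint mode \code{drugGroup}.
#' @export
makeFolds <- function(ddiTable, k = 5L, mode = c("pair", "drug-disjoint"),
                      rngSeed = 1L) {
  mode <- match.arg(mode)
  k <- as.integer(k)
  if (k < 2L) stop("fold count k must be >= 2")
  n <- nrow(ddiTable)
  set.seed(rngSeed)
  if (mode == "pair") {
    fold <- integer(n)
    tab <- table(ddiTable$label)
    small <- as.integer(names(tab)[tab < k])
    strata <- ifelse(ddiTable$label %in% small, -1L, ddiTable$label)
    for (s in unique(strata)) {
      idx <- which(strata == s)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    list(fold = fold, mode = mode, k = k,
         remainderClasses = small)
  } else {
    drugs <- sort(unique(c(ddiTable$drug_a, ddiTable$drug_b)))
    grp <- rep_len(seq_len(k), length(drugs))[sample.int(length(drugs))]
    names(grp) <- drugs
    ga <- grp[ddiTable$drug_a]
    gb <- grp[ddiTable$drug_b]
    fold <- ifelse(ga == gb, ga, 0L)  # cross-group pairs belong to no test fold
    list(fold = as.integer(fold), mode = mode, k = k,
         remainderClasses = integer(0), drugGroup = grp)
  }
}

#' Train/test drug overlap certificate for one fold
#'
#' @param ddiTable DDI table.
#' @param plan From \code{\link{makeFolds}}.
#' @param fold Fold index.
#' @return List with the train/test pair indices and
#'   \code{sharedDrugs} (must be empty in drug-disjoint mode).
#' @export
foldSplit <- function(ddiTable, plan, fold) {
  testIdx <- which(plan$fold == fold)
  trainIdx <- if (plan$mode == "pair") {
    which(plan$fold != fold)
  } else {
    grp <- plan$drugGroup
    which(grp[ddiTable$drug_a] != fold & grp[ddiTable$drug_b] != fold)
  }
  trainDrugs <- unique(c(ddiTable$drug_a[trainIdx],
                         ddiTable$drug_b[trainIdx]))
  testDrugs <- unique(c(ddiTable$drug_a[testIdx],
                        ddiTable$drug_b[testIdx]))
  list(train = trainIdx, test = testIdx,
       sharedDrugs = intersect(trainDrugs, testDrugs))
}

#' Early-stopping decision on a validation-accuracy trace
#'
#' The rule used by \code{\link{trainFold}}: training halts after
#' \code{patience} consecutive epochs without improvement over the best
#' validation accuracy so far, and the best epoch's checkpoint is kept.
#'
#' @param valAcc Numeric vector of per-epoch validation accuracies.
#' @param patience Consecutive non-improving epochs tolerated.
#' @return List with \code{stopEpoch} (last epoch run; length(valAcc)
#'   when no stop triggers) and \code{bestEpoch}.
#' @export
earlyStopTrace <- function(valAcc, patience = 10L) {
  best <- -Inf
  bestEpoch <- 0L
  since <- 0L
  for (e in seq_along(valAcc)) {
    if (valAcc[e] > best) {
      best <- valAcc[e]
      bestEpoch <- e
      since <- 0L
    } else {
      since <- since + 1L
      if (since >= patience) return(list(stopEpoch = e, bestEpoch = bestEpoch))
    }
  }
  list(stopEpoch = length(valAcc), bestEpoch = bestEpoch)
}

#' Train the fused model on one fold
#'
#' Full-batch training: each epoch encodes every drug in the train/val
#' pair set once, fuses pair features, and takes one Adam step on the
#' cross-entropy; validation accuracy drives early stopping (patience
#' from the config) and the best-validation-epoch checkpoint is restored
#' into the model before returning. The per-epoch history (epoch,
#' train_loss, train_acc, val_acc) is returned and optionally written as
#' CSV.
#'
#' @param model From \code{\link{createModel}} (modified in place:
#'   parameters end at the best epoch).
#' @param preps From \code{\link{prepareDrugInputs}}.
#' @param trainPairs,valPairs Disjoint DDI tables; labels are 0-based
#'   class indices.
#' @param config RunConfig.
#' @param historyCsv Optional path for the CSV training log.
#' @return List with \code{history}, \code{bestEpoch}, \code{stopEpoch},
#'   \code{bestValAcc}.
#' @export
trainFold <- function(model, preps, trainPairs, valPairs,
                      config = model$config, historyCsv = NULL) {
  if (nrow(trainPairs) == 0L) stop("empty training set")
  if (config$symmetrizePairs) {
    sw <- trainPairs
    names(sw)[1:2] <- c("drug_b", "drug_a")
    trainPairs <- rbind(trainPairs, sw[, names(trainPairs)])
  }
  yTrain <- trainPairs$label + 1L
  yVal <- valPairs$label + 1L
  set.seed(deriveSeed(config$seed, 23L))
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     train_acc = numeric(0), val_acc = numeric(0))
  best <- -Inf
  bestEpoch <- 0L
  since <- 0L
  snap <- modelSnapshot(model)
  for (epoch in seq_len(config$maxEpochs)) {
    adTapeBegin()
    adZeroGrad(model$params)
    X <- pairFeatureNodes(model, preps, trainPairs)
    logits <- headForward(model$head, X, training = TRUE)
    loss <- adCrossEntropy(logits, yTrain)
    adBackward(loss)
    trainAcc <- mean(max.col(loss$probs, ties.method = "first") == yTrain)
    adClipGradNorm(model$params, maxNorm = 5)
    adamStep(model$params, lr = config$lr, beta1 = config$beta1,
             beta2 = config$beta2)
    adTapeEnd()
    valAcc <- if (nrow(valPairs)) {
      p <- predictPairs(model, preps, valPairs)
      mean(max.col(p, ties.method = "first") == yVal)
    } else trainAcc
    hist <- rbind(hist, data.frame(epoch = epoch,
                                   train_loss = as.numeric(loss$value),
                                   train_acc = trainAcc, val_acc = valAcc))
    if (valAcc > best) {
      best <- valAcc
      bestEpoch <- epoch
      since <- 0L
      snap <- modelSnapshot(model)
    } else {
      since <- since + 1L
      if (since >= config$patience) break
    }
  }
  modelRestore(model, snap)
  if (!is.null(historyCsv)) utils::write.csv(hist, historyCsv,
                                             row.names = FALSE)
  list(history = hist, bestEpoch = bestEpoch, stopEpoch = nrow(hist),
       bestValAcc = best)
}

#' Classification metric report
#'
#' Accuracy, per-class precision/recall/F1 with support, macro and
#' support-weighted averages. Per-class values whose denominator is zero
#' are reported as 0 and flagged in \code{zeroDivision} rather than
#' dropped silently. With \code{probs} for a 2-class task, ROC-AUC
#' (rank/Mann-Whitney identity) and PR-AUC (precision steps averaged over
#' recall) are added.
#'
#' @param truth Integer true labels (0-based).
#' @param pred Integer predicted labels (0-based).
#' @param probs Optional n x C probability matrix (binary metrics use
#'   column 2 as the positive-class score).
#' @param C Class count (default: max label + 1).
#' @return List with \code{accuracy}, \code{perClass} (data.frame),
#'   \code{macro}, \code{weighted}, \code{zeroDivision}, and optionally
#'   \code{rocAuc}, \code{prAuc}.
#' @export
metricReport <- function(truth, pred, probs = NULL,
                         C = max(c(truth, pred)) + 1L) {
  if (length(truth) == 0L) stop("empty test set")
  stopifnot(length(truth) == length(pred))
  classes <- 0:(C - 1L)
  tp <- fp <- fn <- numeric(C)
  for (i in seq_len(C)) {
    c0 <- classes[i]
    tp[i] <- sum(truth == c0 & pred == c0)
    fp[i] <- sum(truth != c0 & pred == c0)
    fn[i] <- sum(truth == c0 & pred != c0)
  }
  support <- tp + fn
  div <- function(a, b) ifelse(b == 0, 0, a / b)
  precision <- div(tp, tp + fp)
  recall <- div(tp, tp + fn)
  f1 <- div(2 * precision * recall, precision + recall)
  zeroDiv <- classes[(tp + fp) == 0 | (tp + fn) == 0 |
                     (precision + recall) == 0]
  present <- support > 0
  w <- support / sum(support)
  report <- list(
    accuracy = mean(truth == pred),
    perClass = data.frame(class = classes, precision = precision,
                          recall = recall, f1 = f1, support = support),
    macro = c(precision = mean(precision[present]),
              recall = mean(recall[present]),
              f1 = mean(f1[present])),
    weighted = c(precision = sum(w * precision),
                 recall = sum(w * recall),
                 f1 = sum(w * f1)),
    zeroDivision = zeroDiv)
  if (!is.null(probs) && C == 2L) {
    score <- probs[, 2L]
    pos <- score[truth == 1L]
    neg <- score[truth == 0L]
    if (length(pos) && length(neg)) {
      r <- rank(c(pos, neg))
      report$rocAuc <- (sum(r[seq_along(pos)]) -
                        length(pos) * (length(pos) + 1) / 2) /
        (length(pos) * length(neg))
      report$prAuc <- .prAuc(truth, score)
    }
  }
  report
}

## average precision (step-wise PR curve integration)
.prAuc <- function(truth, score) {
  ord <- order(score, decreasing = TRUE)
  y <- truth[ord] == 1L
  tp <- cumsum(y)
  prec <- tp / seq_along(y)
  sum(prec[y]) / sum(y)
}

#' Evaluate a trained model on a pair set
#' @param model Trained model.
#' @param preps From \code{\link{prepareDrugInputs}}.
#' @param pairs DDI table.
#' @return A \code{\link{metricReport}}.
#' @export
evaluateModel <- function(model, preps, pairs) {
  if (nrow(pairs) == 0L) stop("empty test set")
  probs <- predictPairs(model, preps, pairs)
  metricReport(pairs$label, max.col(probs, ties.method = "first") - 1L, probs = probs,
               C = model$C)
}

#' Stratified cross-validation of the fused model
#'
#' For each fold: test on the fold, validate on the next fold, train on
#' the rest; a fresh model is initialized per fold. The per-drug inputs
#' (including the subgraph matrices M_d) are computed once and reused
#' byte-identically across folds; the serialized M_d inputs are compared
#' per fold and recorded in \code{frozenFeatureCheck}.
#'
#' @param drugTable,ddiTable Filtered tables.
#' @param vocab Vocabulary built on the drug table's SMILES.
#' @param config RunConfig.
#' @param subgraphs,store KG inputs for KG-using variants.
#' @param outDir Optional directory for per-fold CSV logs.
#' @return List with per-fold reports, mean accuracy, fold plan and
#'   \code{frozenFeatureCheck} (all folds saw byte-identical M_d).
#' @export
crossValidate <- function(drugTable, ddiTable, vocab, config = runConfig(),
                          subgraphs = NULL, store = NULL, outDir = NULL) {
  C <- max(ddiTable$label) + 1L
  preps <- prepareDrugInputs(drugTable, vocab, config, subgraphs, store)
  mdBytes <- serialize(lapply(preps, `[[`, "M"), NULL)
  plan <- makeFolds(ddiTable, k = config$folds,
                    mode = if (config$split == "pair") "pair"
                           else "drug-disjoint",
                    rngSeed = deriveSeed(config$seed, 31L))
  reports <- vector("list", config$folds)
  frozenOk <- TRUE
  shared <- integer(config$folds)
  for (f in seq_len(config$folds)) {
    sp <- foldSplit(ddiTable, plan, f)
    if (config$folds >= 3L) {
      valFold <- f %% config$folds + 1L
      valIdx <- intersect(sp$train, which(plan$fold == valFold))
    } else {
      ## with k = 2 the only other fold is the training set; hold out a
      ## seeded 25% of it for validation instead
      set.seed(deriveSeed(config$seed, 37L + f))
      valIdx <- sort(sample(sp$train, max(1L, length(sp$train) %/% 4L)))
    }
    trIdx <- setdiff(sp$train, valIdx)
    if (length(trIdx) == 0L || length(sp$test) == 0L) next
    model <- createModel(config, vocab, C)
    frozenOk <- frozenOk &&
      identical(serialize(lapply(preps, `[[`, "M"), NULL), mdBytes)
    fit <- trainFold(model, preps, ddiTable[trIdx, , drop = FALSE],
                     ddiTable[valIdx, , drop = FALSE], config,
                     historyCsv = if (!is.null(outDir))
                       file.path(outDir, sprintf("fold%d_history.csv", f)))
    reports[[f]] <- evaluateModel(model, preps,
                                  ddiTable[sp$test, , drop = FALSE])
    reports[[f]]$bestEpoch <- fit$bestEpoch
    shared[f] <- length(sp$sharedDrugs)
  }
  done <- !vapply(reports, is.null, TRUE)
  list(folds = reports, plan = plan,
       meanAccuracy = mean(vapply(reports[done], `[[`, 0, "accuracy")),
       sharedDrugCounts = shared,
       frozenFeatureCheck = frozenOk)
}

#' Run one ablation variant end-to-end
#'
#' Rebuilds the fusion vector with only the variant's blocks (and, for
#' the KG variants, the requested subgraph mode) under the otherwise
#' identical training protocol.
#'
#' @param variant See \code{\link{ablationBlocks}}.
#' @param drugTable,ddiTable,vocab,config,subgraphs,store As in
#'   \code{\link{crossValidate}}; \code{subgraphs} should be the
#'   pathway-anchored set and \code{rwSubgraphs} the raw random-walk
#'   neighborhoods (used by the \code{kg-rw} modes).
#' @param rwSubgraphs Optional named list of raw-neighborhood subgraphs.
#' @return The \code{\link{crossValidate}} result.
#' @export
runAblation <- function(variant, drugTable, ddiTable, vocab,
                        config = runConfig(), subgraphs = NULL,
                        store = NULL, rwSubgraphs = NULL) {
  blocks <- ablationBlocks(variant)
  config$ablation <- variant
  subs <- if (!blocks$kg) NULL
          else if (blocks$anchored) subgraphs
          else rwSubgraphs %||% subgraphs
  crossValidate(drugTable, ddiTable, vocab, config, subgraphs = subs,
                store = store)
}
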