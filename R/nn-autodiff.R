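## Minimal reverse-mode automatic differentiation over dense matrices.
##
## Every value in the computation graph is an environment ("node") holding a
## numeric matrix in $value and an accumulated gradient in $grad. Operations
## record themselves on a tape (creation order); adBackward() replays the
## tape in reverse. Parameters are nodes created off-tape that persist across
## tapes; their gradients are zeroed explicitly before each forward pass.
##
## This core exists because the model components (Transformer encoder, GAT,
## convolutional set aggregator, MLP head) are trained jointly with Adam and
## no deep-learning framework is part of this package's dependency set.

.ad <- new.env(parent = emptyenv())
.ad$tape <- NULL
.ad$k <- 0L

#' Start a fresh autodiff tape
#'
#' Clears the operation tape. Call once per forward/backward pass.
#' @return Invisibly, NULL.
#' @keywords internal
adTapeBegin <- function() {
  .ad$tape <- vector("list", 4096L)
  .ad$k <- 0L
  invisible(NULL)
}

#' Discard the current tape
#' @keywords internal
adTapeEnd <- function() {
  .ad$tape <- NULL
  .ad$k <- 0L
  invisible(NULL)
}

adRecord <- function(node) {
  if (!is.null(.ad$tape)) {
    k <- .ad$k + 1L
    if (k > length(.ad$tape)) .ad$tape <- c(.ad$tape, vector("list", length(.ad$tape)))
    .ad$tape[[k]] <- node
    .ad$k <- k
  }
  node
}

adNewNode <- function(value, backfn = NULL, record = TRUE) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$backfn <- backfn
  if (record) adRecord(node)
  node
}

#' Create a trainable parameter node
#'
#' Parameters live off-tape and persist across forward passes.
#' @param value Numeric matrix (or vector, coerced to a 1-row matrix).
#' @return A parameter node.
#' @keywords internal
adParam <- function(value) {
  if (!is.matrix(value)) value <- matrix(value, nrow = 1L)
  node <- adNewNode(value, record = FALSE)
  node$param <- TRUE
  node
}

#' Wrap a constant matrix as a node
#' @keywords internal
adConst <- function(value) {
  if (!is.matrix(value)) value <- matrix(value, nrow = 1L)
  adNewNode(value, record = FALSE)
}

adAccum <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

#' Run backpropagation from a scalar loss node
#' @param loss Node whose value is a 1x1 matrix.
#' @keywords internal
adBackward <- function(loss) {
  stopifnot(length(loss$value) == 1L)
  loss$grad <- matrix(1, 1L, 1L)
  if (.ad$k > 0L) {
    for (i in seq(.ad$k, 1L)) {
      n <- .ad$tape[[i]]
      if (!is.null(n$backfn) && !is.null(n$grad)) n$backfn(n$grad)
    }
  }
  invisible(NULL)
}

#' Zero the gradients of a set of parameter nodes
#' @keywords internal
adZeroGrad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

## ---- primitive operations ------------------------------------------------

adMatmul <- function(a, b) {
  v <- a$value %*% b$value
  adNewNode(v, backfn = function(g) {
    adAccum(a, g %*% t(b$value))
    adAccum(b, t(a$value) %*% g)
  })
}

adTranspose <- function(a) {
  adNewNode(t(a$value), backfn = function(g) adAccum(a, t(g)))
}

adAdd <- function(a, b) {
  stopifnot(all(dim(a$value) == dim(b$value)))
  adNewNode(a$value + b$value, backfn = function(g) {
    adAccum(a, g)
    adAccum(b, g)
  })
}

adSub <- function(a, b) {
  stopifnot(all(dim(a$value) == dim(b$value)))
  adNewNode(a$value - b$value, backfn = function(g) {
    adAccum(a, g)
    adAccum(b, -g)
  })
}

## a: n x m, bias: 1 x m broadcast over rows
adAddBias <- function(a, bias) {
  stopifnot(ncol(a$value) == ncol(bias$value), nrow(bias$value) == 1L)
  adNewNode(sweep(a$value, 2L, as.numeric(bias$value), "+"), backfn = function(g) {
    adAccum(a, g)
    adAccum(bias, matrix(colSums(g), 1L))
  })
}

adMul <- function(a, b) {
  stopifnot(all(dim(a$value) == dim(b$value)))
  adNewNode(a$value * b$value, backfn = function(g) {
    adAccum(a, g * b$value)
    adAccum(b, g * a$value)
  })
}

adScale <- function(a, s) {
  adNewNode(a$value * s, backfn = function(g) adAccum(a, g * s))
}

## elementwise product with a constant matrix
adHadamardConst <- function(a, m) {
  stopifnot(all(dim(a$value) == dim(m)))
  adNewNode(a$value * m, backfn = function(g) adAccum(a, g * m))
}

adLeakyRelu <- function(a, slope = 0.01) {
  d <- ifelse(a$value > 0, 1, slope)
  adNewNode(a$value * d, backfn = function(g) adAccum(a, g * d))
}

adRelu <- function(a) adLeakyRelu(a, 0)

adElu <- function(a, alpha = 1) {
  x <- a$value
  v <- ifelse(x > 0, x, alpha * (exp(pmin(x, 0)) - 1))
  d <- ifelse(x > 0, 1, v + alpha)
  adNewNode(v, backfn = function(g) adAccum(a, g * d))
}

adSigmoid <- function(a) {
  v <- 1 / (1 + exp(-a$value))
  adNewNode(v, backfn = function(g) adAccum(a, g * v * (1 - v)))
}

#' Row-wise softmax restricted to allowed entries
#'
#' @param a Node, n x m matrix of logits.
#' @param mask 0/1 matrix of the same shape; disallowed entries get
#'   probability 0. Rows that allow no entry come back as all-zero rows.
#' @keywords internal
adMaskedSoftmaxRows <- function(a, mask) {
  x <- a$value
  x[mask == 0] <- -Inf
  mx <- apply(x, 1L, max)
  mx[!is.finite(mx)] <- 0
  e <- exp(x - mx)
  e[mask == 0] <- 0
  rs <- rowSums(e)
  rs[rs == 0] <- 1
  s <- e / rs
  adNewNode(s, backfn = function(g) {
    adAccum(a, s * (g - rowSums(g * s)))
  })
}

#' Row-wise layer normalization with learnable gain/shift
#' @keywords internal
adLayerNormRows <- function(a, gamma, beta, eps = 1e-5) {
  x <- a$value
  m <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  va <- rowMeans(xc * xc)
  sd <- sqrt(va + eps)
  xhat <- xc / sd
  gam <- as.numeric(gamma$value)
  v <- sweep(sweep(xhat, 2L, gam, "*"), 2L, as.numeric(beta$value), "+")
  adNewNode(v, backfn = function(g) {
    gy <- sweep(g, 2L, gam, "*")
    ## d xhat -> d x for row-wise normalization
    gx <- (gy - rowMeans(gy) - xhat * rowMeans(gy * xhat)) / sd
    adAccum(a, gx)
    adAccum(gamma, matrix(colSums(g * xhat), 1L))
    adAccum(beta, matrix(colSums(g), 1L))
  })
}

#' Batch normalization over rows (the batch dimension)
#'
#' @param state Environment holding running_mean / running_var, updated in
#'   training mode.
#' @keywords internal
adBatchNorm <- function(a, gamma, beta, state, training = TRUE,
                        momentum = 0.1, eps = 1e-5) {
  x <- a$value
  n <- nrow(x)
  gam <- as.numeric(gamma$value)
  if (training && n > 1L) {
    mu <- colMeans(x)
    xc <- sweep(x, 2L, mu)
    va <- colMeans(xc * xc)
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    state$running_var <- (1 - momentum) * state$running_var +
      momentum * va * n / max(1, n - 1)
    sd <- sqrt(va + eps)
    xhat <- sweep(xc, 2L, sd, "/")
    v <- sweep(sweep(xhat, 2L, gam, "*"), 2L, as.numeric(beta$value), "+")
    adNewNode(v, backfn = function(g) {
      gy <- sweep(g, 2L, gam, "*")
      gx <- sweep(gy, 2L, colMeans(gy)) -
        xhat * matrix(colMeans(gy * xhat), n, ncol(x), byrow = TRUE)
      gx <- sweep(gx, 2L, sd, "/")
      adAccum(a, gx)
      adAccum(gamma, matrix(colSums(g * xhat), 1L))
      adAccum(beta, matrix(colSums(g), 1L))
    })
  } else {
    sd <- sqrt(state$running_var + eps)
    xhat <- sweep(sweep(x, 2L, state$running_mean), 2L, sd, "/")
    v <- sweep(sweep(xhat, 2L, gam, "*"), 2L, as.numeric(beta$value), "+")
    adNewNode(v, backfn = function(g) {
      adAccum(a, sweep(sweep(g, 2L, gam, "*"), 2L, sd, "/"))
      adAccum(gamma, matrix(colSums(g * xhat), 1L))
      adAccum(beta, matrix(colSums(g), 1L))
    })
  }
}

#' Inverted dropout (scales kept units by 1/(1-p))
#' @keywords internal
adDropout <- function(a, p, training = TRUE) {
  if (!training || p <= 0) return(a)
  keep <- matrix(stats::runif(length(a$value)) >= p, nrow(a$value)) / (1 - p)
  adHadamardConst(a, keep)
}

#' Column-bind nodes
#' @keywords internal
adConcatCols <- function(nodes) {
  vals <- lapply(nodes, function(n) n$value)
  widths <- vapply(vals, ncol, integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  adNewNode(do.call(cbind, vals), backfn = function(g) {
    for (i in seq_along(nodes)) {
      adAccum(nodes[[i]], g[, starts[i]:ends[i], drop = FALSE])
    }
  })
}

#' Row-bind nodes (each contributing its own rows)
#' @keywords internal
adStackRows <- function(nodes) {
  vals <- lapply(nodes, function(n) n$value)
  heights <- vapply(vals, nrow, integer(1))
  ends <- cumsum(heights)
  starts <- ends - heights + 1L
  adNewNode(do.call(rbind, vals), backfn = function(g) {
    for (i in seq_along(nodes)) {
      adAccum(nodes[[i]], g[starts[i]:ends[i], , drop = FALSE])
    }
  })
}

#' Mean of the full matrix as a 1x1 node
#' @keywords internal
adMeanAll <- function(a) {
  n <- length(a$value)
  adNewNode(matrix(mean(a$value), 1L, 1L), backfn = function(g) {
    adAccum(a, matrix(as.numeric(g) / n, nrow(a$value), ncol(a$value)))
  })
}

#' Columnwise max over a subset of rows
#' @keywords internal
adColMaxRows <- function(a, rows) {
  x <- a$value[rows, , drop = FALSE]
  idx <- apply(x, 2L, which.max)
  v <- matrix(x[cbind(idx, seq_len(ncol(x)))], 1L)
  adNewNode(v, backfn = function(g) {
    gx <- matrix(0, nrow(a$value), ncol(a$value))
    gx[cbind(rows[idx], seq_len(ncol(x)))] <- as.numeric(g)
    adAccum(a, gx)
  })
}

#' Mean cross-entropy of softmax(logits) against integer class labels
#'
#' Numerically stable fused softmax + NLL. Labels are 1-based class indices.
#' @return Node with a 1x1 value; $probs carries the softmax matrix.
#' @keywords internal
adCrossEntropy <- function(logits, labels) {
  x <- logits$value
  n <- nrow(x)
  stopifnot(length(labels) == n)
  mx <- apply(x, 1L, max)
  e <- exp(x - mx)
  p <- e / rowSums(e)
  picked <- p[cbind(seq_len(n), labels)]
  loss <- -mean(log(pmax(picked, 1e-12)))
  node <- adNewNode(matrix(loss, 1L, 1L), backfn = function(g) {
    y <- matrix(0, n, ncol(x))
    y[cbind(seq_len(n), labels)] <- 1
    adAccum(logits, (p - y) * (as.numeric(g) / n))
  })
  node$probs <- p
  node
}

## ---- optimizer -----------------------------------------------------------

#' One Adam update over a list of parameter nodes
#'
#' Moment buffers are kept on the parameter nodes themselves.
#' @keywords internal
adamStep <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  for (p in params) {
    if (is.null(p$grad)) next
    if (is.null(p$adam_m)) {
      p$adam_m <- matrix(0, nrow(p$value), ncol(p$value))
      p$adam_v <- p$adam_m
      p$adam_t <- 0L
    }
    p$adam_t <- p$adam_t + 1L
    p$adam_m <- beta1 * p$adam_m + (1 - beta1) * p$grad
    p$adam_v <- beta2 * p$adam_v + (1 - beta2) * p$grad^2
    mhat <- p$adam_m / (1 - beta1^p$adam_t)
    vhat <- p$adam_v / (1 - beta2^p$adam_t)
    p$value <- p$value - lr * mhat / (sqrt(vhat) + eps)
  }
  invisible(NULL)
}

#' Clip gradients to a global norm bound
#' @keywords internal
adClipGradNorm <- function(params, maxNorm = 5) {
  tot <- sqrt(sum(vapply(params, function(p)
    if (is.null(p$grad)) 0 else sum(p$grad^2), 0)))
  if (is.finite(tot) && tot > maxNorm) {
    s <- maxNorm / tot
    for (p in params) if (!is.null(p$grad)) p$grad <- p$grad * s
  }
  invisible(NULL)
}

#' Collect parameter nodes from a nested structure
#' @keywords internal
adCollectParams <- function(x) {
  out <- list()
  walk <- function(v) {
    if (is.environment(v)) {
      if (isTRUE(v$param)) out[[length(out) + 1L]] <<- v
    } else if (is.list(v)) {
      for (el in v) walk(el)
    }
  }
  walk(x)
  out
}

#' Snapshot / restore parameter values (checkpointing)
#' @keywords internal
adSnapshot <- function(params) lapply(params, function(p) p$value)

#' @keywords internal
adRestore <- function(params, snap) {
  stopifnot(length(params) == length(snap))
  for (i in seq_along(params)) params[[i]]$value <- snap[[i]]
  invisible(NULL)
}
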