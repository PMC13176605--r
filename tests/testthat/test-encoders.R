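tfSetup <- function(seed = 4, L = 12, nLayers = 1) {
  set.seed(seed)
  v <- buildVocab(c("CCO", "c1ccccc1", "CC(C)C"))
  params <- transformerInit(vocabSize(v), dEmb = 8, dModel = 8,
                            nLayers = nLayers, nHead = 2, dFf = 16)
  list(v = v, params = params, L = L)
}

test_that("transformer output is exactly invariant to padded tail length", {
  s <- tfSetup()
  adTapeBegin()
  z1 <- encodeSequence(encodeSmiles("CCO", s$v, L = 8), s$params, L = 8)
  z2 <- encodeSequence(encodeSmiles("CCO", s$v, L = 24), s$params, L = 24)
  adTapeEnd()
  expect_identical(z1$value, z2$value)
})

test_that("an empty encoder stack returns the projected <CLS> embedding", {
  s <- tfSetup(nLayers = 0)
  seq <- encodeSmiles("CCO", s$v, L = 8)
  adTapeBegin()
  z <- encodeSequence(seq, s$params, L = 8)$value
  adTapeEnd()
  cls <- s$params$tokEmb$value[3, , drop = FALSE]  # <CLS> has ID 2
  expected <- cls %*% s$params$Wproj$value + s$params$bproj$value
  expect_equal(z, expected)
})

test_that("sequence branch distinguishes token content; token order enters via the graph branch", {
  s <- tfSetup()
  adTapeBegin()
  za <- encodeSequence(encodeSmiles("CCO", s$v, L = 8), s$params, L = 8)
  zb <- encodeSequence(encodeSmiles("CCN", s$v, L = 8), s$params, L = 8)
  zc <- encodeSequence(encodeSmiles("OCC", s$v, L = 8), s$params, L = 8)
  adTapeEnd()
  # different token multisets separate
  expect_gt(max(abs(za$value - zb$value)), 1e-8)
  # with no positional-encoding module in this branch, reordering the
  # same tokens leaves the <CLS> representation unchanged: order-aware
  # signals live in the graph branch's damped sinusoidal features
  expect_equal(zc$value, za$value, tolerance = 1e-10)
})

test_that("sequence length must match the configured L", {
  s <- tfSetup()
  expect_error(encodeSequence(encodeSmiles("CCO", s$v, L = 16),
                              s$params, L = 8), "does not match")
})

gatSetup <- function(seed = 5, L = 6, kHeads = 2, dPrime = 4, dIn = 4) {
  set.seed(seed)
  params <- gatInit(dIn, kHeads = kHeads, dPrime = dPrime)
  A <- matrix(0, L, L)
  A[2, 3] <- A[3, 2] <- 1
  A[3, 4] <- A[4, 3] <- 2
  diag(A)[2:4] <- 1
  H <- matrix(rnorm(L * dIn), L, dIn)
  H[c(1, 5, 6), ] <- 0
  list(params = params, A = A, H = H,
       atomMask = c(FALSE, TRUE, TRUE, TRUE, FALSE, FALSE))
}

test_that("attention is a proper distribution over each neighborhood", {
  g <- gatSetup()
  adTapeBegin()
  at <- gatAttention(g$H, g$A, g$params$heads[[1]])
  alpha <- at$alpha$value
  adTapeEnd()
  # rows with neighbors sum to 1; non-edges are exactly zero
  for (i in 2:4) expect_equal(sum(alpha[i, ]), 1, tolerance = 1e-12)
  expect_true(all(alpha[g$A == 0] == 0))
  # a node whose only neighbor is its self-loop takes weight 1
  A1 <- matrix(0, 3, 3); A1[2, 2] <- 1
  adTapeBegin()
  a1 <- gatAttention(matrix(rnorm(12), 3, 4), A1,
                     g$params$heads[[1]])$alpha$value
  adTapeEnd()
  expect_equal(a1[2, 2], 1)
  # two neighbors with identical features split attention evenly
  A2 <- matrix(0, 3, 3); A2[1, 2] <- A2[1, 3] <- A2[2, 1] <- A2[3, 1] <- 1
  H2 <- rbind(rnorm(4), c(1, 2, 3, 4), c(1, 2, 3, 4))
  adTapeBegin()
  a2 <- gatAttention(H2, A2, g$params$heads[[1]])$alpha$value
  adTapeEnd()
  expect_equal(unname(a2[1, 2:3]), c(0.5, 0.5))
})

test_that("a GAT layer concatenates K heads of width dPrime", {
  g <- gatSetup(kHeads = 4, dPrime = 4)
  adTapeBegin()
  out <- gatLayer(g$H, g$A, g$params)$value
  adTapeEnd()
  expect_equal(ncol(out), 16L)
  # zero features give zero pre-activations, hence ELU(0) = 0 outputs
  adTapeBegin()
  z <- gatLayer(matrix(0, 6, 4), g$A, g$params)$value
  adTapeEnd()
  expect_equal(z, matrix(0, 6, 16))
})

test_that("K = 1 with identity weights and a lone self-loop reduces to sigma(h)", {
  set.seed(6)
  params <- gatInit(3, kHeads = 1, dPrime = 3)
  params$heads[[1]]$W$value <- diag(3)
  A <- matrix(0, 2, 2); A[2, 2] <- 1
  H <- matrix(rnorm(6), 2, 3)
  adTapeBegin()
  out <- gatLayer(H, A, params)$value
  adTapeEnd()
  expect_equal(out[2, ], ifelse(H[2, ] > 0, H[2, ], exp(H[2, ]) - 1))
})

test_that("message locality: features of non-neighbors cannot reach a node", {
  g <- gatSetup()
  probe <- function(H) {
    adTapeBegin()
    out <- gatLayer(H, g$A, g$params)$value
    adTapeEnd()
    out
  }
  base <- probe(g$H)
  Hp <- g$H
  Hp[2, ] <- Hp[2, ] + rnorm(4)  # node 2 is NOT a neighbor of node 4
  pert <- probe(Hp)
  expect_equal(pert[4, ], base[4, ], tolerance = 1e-12)
  expect_gt(max(abs(pert[3, ] - base[3, ])), 1e-8)  # but 3 sees 2
})

test_that("GAT layers are equivariant and the readout invariant under relabeling", {
  for (rep in 1:3) {
    set.seed(rep)
    L <- 8
    params <- gatInit(5, kHeads = 2, dPrime = 3)
    A <- matrix(0, L, L)
    for (i in 2:L) {
      j <- sample(2:L, 1)
      A[i, j] <- A[j, i] <- sample(c(1, 1.5, 2), 1)
    }
    diag(A)[2:L] <- 1
    H <- matrix(rnorm(L * 5), L, 5)
    H[1, ] <- 0
    atomMask <- c(FALSE, rep(TRUE, L - 1))
    perm <- c(1, 1 + sample(L - 1))  # keep the non-atom slot in place
    adTapeBegin()
    out <- gatLayer(H, A, params)$value
    outP <- gatLayer(H[perm, ], A[perm, perm], params)$value
    r1 <- gatReadout(gatLayer(H, A, params), atomMask, params,
                     mode = "mean")$value
    r2 <- gatReadout(gatLayer(H[perm, ], A[perm, perm], params),
                     atomMask[perm], params, mode = "mean")$value
    adTapeEnd()
    expect_equal(outP, out[perm, ], tolerance = 1e-10)
    expect_equal(r2, r1, tolerance = 1e-10)
  }
})

test_that("readout modes agree on degenerate inputs and respect the residual", {
  g <- gatSetup()
  set.seed(8)
  node <- adConst(matrix(rep(rnorm(8), each = 6), 6, 8))  # identical rows
  params <- gatInit(4, kHeads = 2, dPrime = 4)
  adTapeBegin()
  m1 <- gatReadout(node, g$atomMask, params, mode = "mean")$value
  m2 <- gatReadout(node, g$atomMask, params, mode = "max")$value
  adTapeEnd()
  expect_equal(m1, m2, tolerance = 1e-12)
  # zero-initialized final MLP layer makes the readout a pure identity
  params$mlpW2$value[] <- 0
  params$mlpB2$value[] <- 0
  single <- adConst(matrix(rnorm(48), 6, 8))
  am <- c(FALSE, TRUE, rep(FALSE, 4))  # single-atom molecule
  adTapeBegin()
  r <- gatReadout(single, am, params, mode = "mean")$value
  adTapeEnd()
  expect_equal(r, single$value[2, , drop = FALSE])
  expect_error(gatReadout(single, rep(FALSE, 6), params), "at least one atom")
})

test_that("gradients flow through both encoder branches (finite differences)", {
  set.seed(9)
  v <- buildVocab("CCO")
  tp <- transformerInit(vocabSize(v), dEmb = 4, dModel = 4, nLayers = 1,
                        nHead = 2, dFf = 8)
  seq <- encodeSmiles("CCO", v, L = 6)
  fwdT <- function() adMeanAll(encodeSequence(seq, tp, L = 6))
  adTapeBegin(); adZeroGrad(list(tp$tokEmb, tp$layers[[1]]$Wq))
  loss <- fwdT(); adBackward(loss); adTapeEnd()
  for (p in list(tp$tokEmb, tp$layers[[1]]$Wq))
    expect_lt(max(abs(p$grad - numericalGrad(fwdT, p))), 1e-6)

  gp <- gatInit(4, kHeads = 1, dPrime = 3)
  graph <- smilesToGraph(smilesTokenize("CCO"), L = 6)
  emb <- adParam(matrix(rnorm(vocabSize(v) * 4), vocabSize(v), 4))
  P <- positionalEncoding(6, 4)
  fwdG <- function() adMeanAll(encodeGraph(seq, graph, gp, emb, P = P))
  plist <- list(emb, gp$heads[[1]]$W, gp$heads[[1]]$a1, gp$mlpW1)
  adTapeBegin(); adZeroGrad(plist); loss <- fwdG(); adBackward(loss)
  adTapeEnd()
  for (p in plist)
    expect_lt(max(abs(p$grad - numericalGrad(fwdG, p))), 1e-6)
})
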