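ns <- asNamespace("graphDDI")

test_that("SMILES tokenizer handles multi-character elements and unknowns", {
  expect_length(tokenizeSmiles("CCO"), 3)
  expect_length(tokenizeSmiles("CCl"), 2)
  expect_length(tokenizeSmiles("BrCBr"), 3)
  expect_equal(tokenizeSmiles("X"), 1L)  # <unk>
  toks <- tokenizeSmiles("c1ccccc1")
  expect_length(toks, 8)
})

test_that("cross-attention degeneracies and oracle agreement", {
  set.seed(61)
  ## L = 1: every atom fully attends to the single token
  n <- 4; ds <- 3
  Qg <- matrix(rnorm(n * ds), n, ds)
  Tk <- matrix(rnorm(1 * ds), 1, ds)
  Tv <- matrix(rnorm(1 * 2), 1, 2)
  tape <- ns$adTape()
  out <- ns$adBlockCrossAttention(ns$adLeaf(tape, Qg), ns$adLeaf(tape, Tk),
                                  ns$adLeaf(tape, Tv), n, 1L)
  for (i in seq_len(n)) expect_equal(ns$adVal(out)[i, ], Tv[1, ])

  ## identical token states: attended rows independent of scores
  L <- 5
  Tk2 <- matrix(rnorm(L * ds), L, ds)
  Tv2 <- matrix(rep(rnorm(2), each = L), L, 2)
  out2 <- ns$adBlockCrossAttention(ns$adLeaf(tape, Qg), ns$adLeaf(tape, Tk2),
                                   ns$adLeaf(tape, Tv2), n, L)
  for (i in seq_len(n)) expect_equal(ns$adVal(out2)[i, ], Tv2[1, ],
                                     tolerance = 1e-12)

  ## elementwise exp/normalize oracle on a hand-set 3x2 score system
  n <- 3; L <- 2
  Qg3 <- matrix(rnorm(n * ds), n, ds)
  Tk3 <- matrix(rnorm(L * ds), L, ds)
  Tv3 <- matrix(rnorm(L * 4), L, 4)
  out3 <- ns$adVal(ns$adBlockCrossAttention(
    ns$adLeaf(tape, Qg3), ns$adLeaf(tape, Tk3), ns$adLeaf(tape, Tv3),
    n, L))
  for (i in seq_len(n)) {
    z <- numeric(L)
    for (j in seq_len(L)) z[j] <- sum(Qg3[i, ] * Tk3[j, ]) / sqrt(ds)
    a <- exp(z) / sum(exp(z))
    ref <- colSums(Tv3 * a)
    expect_equal(out3[i, ], ref, tolerance = 1e-6)
    expect_equal(sum(a), 1, tolerance = 1e-6)
  }
})

test_that("adaptive fusion: convexity, hand-set gate, and saturation limits", {
  set.seed(62)
  cfg <- tinyConfig()
  model <- initModel(cfg)
  d <- cfg$d_model

  ## h_graph = h_smiles = v  ->  h_final = v regardless of the gate
  smiles <- c("CCO", "CCN")
  drugs <- makeDrugSet(c("a", "b"), smiles)
  cache <- precomputeDrugs(drugs, cfg)
  tape <- ns$adTape()
  leaves <- ns$paramLeaves(tape, model@params)
  enc <- ns$encodeBatch(tape, leaves, cache, cfg)
  lam <- ns$adVal(enc$lambda)
  expect_true(all(lam > 0 & lam < 1))
  hm <- ns$adVal(enc$h_mol)
  ## reconstruct h_final from the published combination rule
  hs <- ns$adVal(ns$adLinear(enc$h_smiles, leaves$W_sproj, leaves$b_sproj))
  expect_equal(ns$adVal(enc$h_final),
               hm * as.numeric(lam) + hs * (1 - as.numeric(lam)),
               tolerance = 1e-10)

  ## lambda = 0.25 arithmetic
  expect_equal(0.25 * c(1, 0) + 0.75 * c(0, 1), c(0.25, 0.75))

  ## forcing the gate bias to +/- 12 saturates toward one modality
  m2 <- model
  m2@params$W_gate2[] <- 0
  m2@params$b_gate2[] <- 12
  tape2 <- ns$adTape()
  leaves2 <- ns$paramLeaves(tape2, m2@params)
  enc2 <- ns$encodeBatch(tape2, leaves2, cache, cfg)
  expect_equal(ns$adVal(enc2$h_final), ns$adVal(enc2$h_mol),
               tolerance = 1e-4)
})

test_that("fusion bypass and fixed-gate ablations run and differ", {
  set.seed(63)
  smiles <- randomMolecules(4, seed = 63)
  mNoF <- initModel(tinyConfig(fusion_on = FALSE))
  h <- encodeSmiles(smiles, mNoF)
  expect_true(all(is.finite(h)))
  expect_false("tok_embed" %in% names(mNoF@params))

  mFix <- initModel(tinyConfig(adaptive_fusion_on = FALSE))
  h2 <- encodeSmiles(smiles, mFix)
  expect_true(all(is.finite(h2)))
  expect_false("W_gate1" %in% names(mFix@params))
})

test_that("fusion responds continuously to gate perturbations", {
  set.seed(64)
  cfg <- tinyConfig()
  model <- initModel(cfg)
  smiles <- c("CCO", "c1ccccc1")
  h0 <- encodeSmiles(smiles, model)
  eps <- 1e-4
  m2 <- model
  m2@params$b_gate2[] <- m2@params$b_gate2[] + eps
  h1 <- encodeSmiles(smiles, m2)
  expect_lt(max(abs(h1 - h0)), 1)  # O(eps) change, not a jump
  expect_gt(max(abs(h1 - h0)), 0)
})

test_that("sequence pooling of a length-1 token stream is its token state", {
  set.seed(65)
  tape <- ns$adTape()
  X <- matrix(rnorm(3 * 4), 3, 4)
  pooled <- ns$adSegmentMean(ns$adLeaf(tape, X), c(1L, 2L))
  expect_equal(ns$adVal(pooled)[1, ], X[1, ])
  expect_equal(ns$adVal(pooled)[2, ], colMeans(X[2:3, ]))
})
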