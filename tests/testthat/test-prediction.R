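ns <- asNamespace("graphDDI")

test_that("pair encoding follows the concatenation rule exactly", {
  expect_equal(pairEncode(c(1, 2), c(3, -1)),
               c(1, 2, 3, -1, 3, -2, 2, 3))
  v <- rnorm(5)
  pe <- pairEncode(v, v)
  expect_equal(pe[16:20], rep(0, 5))        # |v - v| block
  expect_equal(pe[11:15], v * v)            # elementwise product block
  ## swap changes only the first two blocks
  a <- rnorm(4); b <- rnorm(4)
  ab <- pairEncode(a, b); ba <- pairEncode(b, a)
  expect_equal(ab[9:16], ba[9:16])
  expect_equal(ab[1:4], ba[5:8])
  expect_error(pairEncode(1:3, 1:2), "length")
})

test_that("prediction head: zero weights give p = 0.5; eval mode is deterministic", {
  cfg <- tinyConfig()
  set.seed(71)
  model <- initModel(cfg)
  for (nm in c("W_head1", "b_head1", "W_head2", "b_head2", "W_head3",
               "b_head3")) {
    model@params[[nm]][] <- 0
  }
  drugs <- makeDrugSet(c("a", "b"), c("CCO", "CCN"))
  pairs <- data.frame(drug_a = "a", drug_b = "b")
  expect_equal(predictPairs(model, drugs, pairs), 0.5)

  set.seed(72)
  model2 <- initModel(cfg)
  p1 <- predictPairs(model2, drugs, pairs)
  p2 <- predictPairs(model2, drugs, pairs)
  expect_identical(p1, p2)
})

test_that("symmetrized predictions are exactly pair-order invariant", {
  set.seed(73)
  cfg <- tinyConfig()
  model <- initModel(cfg)
  smiles <- randomMolecules(10, seed = 73)
  drugs <- makeDrugSet(paste0("D", 1:10), smiles)
  pairs <- data.frame(drug_a = paste0("D", sample(1:10, 50, TRUE)),
                      drug_b = paste0("D", sample(1:10, 50, TRUE)))
  pairs <- pairs[pairs$drug_a != pairs$drug_b, ]
  rev <- data.frame(drug_a = pairs$drug_b, drug_b = pairs$drug_a)
  cache <- precomputeDrugs(drugs, cfg)
  pf <- predictPairs(model, drugs, pairs, symmetrize = TRUE, cache = cache)
  pr <- predictPairs(model, drugs, rev, symmetrize = TRUE, cache = cache)
  expect_identical(pf, pr)
  ## the raw head is typically order-dependent
  rf <- predictPairs(model, drugs, pairs, symmetrize = FALSE, cache = cache)
  rr <- predictPairs(model, drugs, rev, symmetrize = FALSE, cache = cache)
  expect_gt(max(abs(rf - rr)), 0)
})

test_that("binary cross-entropy closed forms and clamping", {
  expect_equal(bceLoss(0.5, 1), log(2))
  expect_equal(bceLoss(c(0.5, 0.5), c(1, 0), "sum"), 2 * log(2))
  ## perfect (clamped) predictions give a near-zero loss
  expect_lt(bceLoss(c(1, 0), c(1, 0)), 1e-6)
  expect_gte(bceLoss(runif(50), rbinom(50, 1, 0.5)), 0)
})

test_that("total loss composes its three terms with the configured weights", {
  p <- c(0.9, 0.2); y <- c(1, 0)
  params <- list(w = matrix(1:2, 1), b = matrix(0.5, 1))
  ctr <- 1.3
  expect_equal(totalLoss(p, y, ctr, params, alpha = 0.5, beta = 1e-5),
               bceLoss(p, y) + 0.5 * 1.3 + 1e-5 * (1 + 4 + 0.25))
  ## alpha = beta = 0 reduces to plain BCE (contrastive-free variant)
  expect_equal(totalLoss(p, y, ctr, params, alpha = 0, beta = 0),
               bceLoss(p, y))
})

test_that("head and total-loss gradients match central differences", {
  set.seed(74)
  cfg <- tinyConfig()
  d4 <- 4 * cfg$d_model
  params <- list(W_head1 = matrix(rnorm(d4 * 8, sd = 0.3), d4, 8),
                 b_head1 = matrix(0, 1, 8),
                 W_head2 = matrix(rnorm(8 * 4, sd = 0.3), 8, 4),
                 b_head2 = matrix(0, 1, 4),
                 W_head3 = matrix(rnorm(4), 4, 1),
                 b_head3 = matrix(0, 1, 1))
  pf <- matrix(rnorm(6 * d4), 6, d4)
  y <- c(1, 0, 1, 1, 0, 0)
  beta <- 1e-3
  lossOf <- function(p) {
    tape <- ns$adTape()
    leaves <- ns$paramLeaves(tape, p)
    lg <- ns$predictionLogits(ns$adLeaf(tape, pf), leaves, cfg)
    as.numeric(ns$adVal(ns$bceLossNode(lg, y))) +
      beta * l2Penalty(p)
  }
  tape <- ns$adTape()
  leaves <- ns$paramLeaves(tape, params)
  lg <- ns$predictionLogits(ns$adLeaf(tape, pf), leaves, cfg)
  loss <- ns$bceLossNode(lg, y)
  ns$adBackward(loss)
  num <- fdGrad(lossOf, params)
  for (nm in names(params)) {
    ana <- ns$adGrad(leaves[[nm]]) + 2 * beta * params[[nm]]
    scale <- max(abs(num[[nm]]), 1e-3)
    expect_lt(max(abs(ana - num[[nm]])) / scale, 1e-4)
  }
})

test_that("stronger L2 regularization shrinks fitted parameter norms", {
  set.seed(75)
  ## fixed toy fit: one linear unit trained by the package optimizer
  X <- matrix(rnorm(60 * 4), 60, 4)
  w0 <- c(2, -1, 0.5, 1)
  y <- as.numeric(X %*% w0 + rnorm(60, sd = 0.1) > 0)
  fitNorm <- function(beta) {
    params <- list(w = matrix(0, 4, 1), b = matrix(0, 1, 1))
    state <- ns$adamInit(params)
    for (it in 1:300) {
      tape <- ns$adTape()
      leaves <- ns$paramLeaves(tape, params)
      lg <- ns$adLinear(ns$adLeaf(tape, X), leaves$w, leaves$b)
      loss <- ns$bceLossNode(lg, y)
      ns$adBackward(loss)
      grads <- ns$paramGrads(leaves)
      grads <- lapply(names(grads), function(nm) {
        grads[[nm]] + 2 * beta * params[[nm]]
      })
      names(grads) <- names(params)
      upd <- ns$adamStep(params, grads, state, lr = 0.05)
      params <- upd$params; state <- upd$state
    }
    sqrt(l2Penalty(params))
  }
  norms <- vapply(c(0, 1e-5, 1e-3, 1e-1), fitNorm, 1)
  expect_true(all(diff(norms) <= 1e-8))
})
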