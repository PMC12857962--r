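test_that("AUC equals the exhaustive concordance oracle on random vectors", {
  ## hand case: predictions (0.9, 0.8, 0.4, 0.2), labels (1, 0, 1, 0)
  expect_equal(aucScore(c(0.9, 0.8, 0.4, 0.2), c(1, 0, 1, 0)), 3 / 4)
  ## ties half-counted, uninformative scores
  expect_equal(aucScore(rep(0.5, 10), rep(0:1, 5)), 0.5)
  expect_equal(aucScore(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)

  set.seed(81)
  for (rep in 1:100) {
    n <- sample(5:40, 1)
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # force some ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    expect_equal(aucScore(scores, labels), aucOracle(scores, labels))
  }
})

test_that("average precision matches the step-interpolated reference to 1e-9", {
  set.seed(82)
  for (rep in 1:100) {
    n <- sample(5:40, 1)
    scores <- round(runif(n), sample(c(1, 2, 6), 1))
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    expect_equal(apScore(scores, labels), apOracle(scores, labels),
                 tolerance = 1e-9)
  }
})

test_that("AUC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(83)
  for (rep in 1:20) {
    scores <- runif(30)
    labels <- rbinom(30, 1, 0.5)
    if (length(unique(labels)) < 2) next
    ref <- suppressMessages(as.numeric(pROC::auc(labels, scores,
                                                 direction = "<")))
    expect_equal(aucScore(scores, labels), ref, tolerance = 1e-12)
  }
})

test_that("the metrics report satisfies its own identities", {
  set.seed(84)
  scores <- runif(200)
  labels <- rbinom(200, 1, 0.5)
  m <- evaluatePredictions(scores, labels)
  expect_equal(m$ACC, (m$TP + m$TN) / 200)
  expect_equal(m$precision, m$TP / (m$TP + m$FP))
  expect_equal(m$recall, m$TP / (m$TP + m$FN))
  expect_equal(m$F1, 2 * m$precision * m$recall / (m$precision + m$recall))
  ## perfect separation
  p <- evaluatePredictions(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))
  expect_equal(p$ACC, 1); expect_equal(p$AUC, 1); expect_equal(p$F1, 1)
  ## single-class labels: rank metrics undefined
  expect_warning(s <- evaluatePredictions(runif(5), rep(1, 5)), "one class")
  expect_true(is.nan(s$AUC))
})

test_that("transductive split fractions are exact to one record and seed-stable", {
  ds <- generateDataset(generatorConfig(n_drugs = 40L, n_pairs = 100L,
                                        seed = 85L))
  sp <- makeSplit(ds$pairs, ds$drugs, "transductive", seed = 85L)
  expect_equal(nrow(sp$train), 60)
  expect_equal(nrow(sp$val), 20)
  expect_equal(nrow(sp$test), 20)
  ## disjoint and exhaustive
  key <- function(df) paste(df$drug_a, df$drug_b)
  allKeys <- c(key(sp$train), key(sp$val), key(sp$test))
  expect_equal(sort(allKeys), sort(key(ds$pairs)))
  sp2 <- makeSplit(ds$pairs, ds$drugs, "transductive", seed = 85L)
  expect_identical(sp, sp2)
  sp3 <- makeSplit(ds$pairs, ds$drugs, "transductive", seed = 86L)
  expect_false(identical(key(sp$train), key(sp3$train)))
})

test_that("inductive splits keep held-out drugs out of training pairs", {
  ds <- generateDataset(generatorConfig(n_drugs = 50L, n_pairs = 400L,
                                        seed = 87L))
  sp <- makeSplit(ds$pairs, ds$drugs, "inductive_random", seed = 87L)
  trainDrugs <- unique(c(sp$train$drug_a, sp$train$drug_b))
  expect_true(all(trainDrugs %in% sp$train_drugs))
  expect_length(intersect(trainDrugs, sp$test_drugs), 0)
  ## every test pair touches at least one held-out drug
  expect_true(all(sp$test$drug_a %in% sp$test_drugs |
                  sp$test$drug_b %in% sp$test_drugs))
})

test_that("scaffold split never places one scaffold on both sides", {
  ds <- generateDataset(generatorConfig(n_drugs = 60L, n_pairs = 300L,
                                        seed = 88L))
  sp <- makeSplit(ds$pairs, ds$drugs, "inductive_scaffold", seed = 88L)
  scafOf <- function(ids) {
    vapply(ids, function(id) {
      g <- getGraph(ds$drugs, id)
      sc <- murckoScaffold(g)
      if (length(sc) == 0) paste0("acyclic:", id) else
        writeSmiles(graphDDI:::inducedSubgraph(g, sc))
    }, "")
  }
  trainScaf <- scafOf(c(sp$train_drugs, sp$val_drugs))
  testScaf <- scafOf(sp$test_drugs)
  shared <- intersect(trainScaf[!startsWith(trainScaf, "acyclic")],
                      testScaf[!startsWith(testScaf, "acyclic")])
  expect_length(shared, 0)
})

test_that("negative sampling balances a positives-only table without duplicates", {
  ds <- generateDataset(generatorConfig(n_drugs = 40L, n_pairs = 200L,
                                        seed = 89L))
  positives <- ds$pairs[ds$pairs$label == 1, ]
  bal <- sampleNegatives(positives, ds$drugs, ratio = 1, seed = 89L)
  expect_equal(sum(bal$label == 0), sum(bal$label == 1))
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  negKeys <- key(bal$drug_a[bal$label == 0], bal$drug_b[bal$label == 0])
  posKeys <- key(positives$drug_a, positives$drug_b)
  expect_length(intersect(negKeys, posKeys), 0)
  expect_false(anyDuplicated(negKeys) > 0)
})
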