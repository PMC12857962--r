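test_that("SMILES parsing builds correct graphs for hand-checked molecules", {
  g <- parseSmiles("CCO")
  expect_equal(numAtoms(g), 3)
  expect_equal(numBonds(g), 2)
  expect_true(all(g@bonds$order == 1))
  expect_false(any(g@atoms$aromatic))
  expect_equal(g@atoms$nH, c(3L, 2L, 1L))

  g <- parseSmiles("c1ccccc1")
  expect_equal(numAtoms(g), 6)
  expect_equal(numBonds(g), 6)
  expect_true(all(g@atoms$aromatic))
  expect_true(all(g@bonds$aromatic))

  ## acetic acid: central carbon carries orders 1 + 2 + 1 = 4, no H
  g <- parseSmiles("CC(=O)O")
  bs <- graphDDI:::bondOrderSums(g@atoms, g@bonds)
  expect_equal(bs[2], 4)
  expect_equal(g@atoms$nH[2], 0L)
  expect_true(validObject(g))
})

test_that("parser reports malformed strings and valence violations", {
  expect_error(parseSmiles("C1CC"), "ring")
  expect_error(parseSmiles("CC%"), "position 3")
  expect_error(parseSmiles("CC)C"), "unmatched")
  expect_error(parseSmiles("C(C)(C)(C)(C)C"), "valence.*atom 1")
  expect_error(parseSmiles(""), "non-empty")
})

test_that("adjacency is symmetric, zero-diagonal and matches the bond list", {
  for (s in fixtureSmiles()) {
    g <- parseSmiles(s)
    A <- g@adjacency
    expect_identical(A, t(A))
    expect_true(all(diag(A) == 0))
    expect_equal(sum(A) / 2, numBonds(g))
  }
})

test_that("featurization is deterministic with exact one-hot structure", {
  sc <- featureSchema()
  g <- featurize(parseSmiles("CCO"), sc)
  expect_equal(nrow(g@atomFeatures), 3)
  expect_equal(ncol(g@atomFeatures), sc$d_atom)
  ## element one-hot block sums to 1 for every atom
  expect_true(all(rowSums(g@atomFeatures[, seq_along(sc$elements)]) == 1))

  b <- featurize(parseSmiles("c1ccccc1"), sc)
  aromCol <- length(sc$elements) + 6 + 5 + 1
  expect_true(all(b@atomFeatures[, aromCol] == 1))

  ## acetic acid bond features: two single one-hots, one double
  ac <- featurize(parseSmiles("CC(=O)O"), sc)
  expect_equal(colSums(ac@bondFeatures[, 1:4]), c(2, 1, 0, 0),
               ignore_attr = TRUE)

  ## purity: repeated call gives bit-identical matrices
  again <- featurize(parseSmiles("CC(=O)O"), sc)
  expect_identical(ac@atomFeatures, again@atomFeatures)
  expect_identical(ac@bondFeatures, again@bondFeatures)
})

test_that("generator SMILES round-trip through parse and re-serialization", {
  smiles <- randomMolecules(25, seed = 11)
  for (s in smiles) {
    g <- parseSmiles(s)
    g2 <- parseSmiles(writeSmiles(g))
    expect_equal(numAtoms(g2), numAtoms(g))
    expect_equal(numBonds(g2), numBonds(g))
    expect_equal(sum(g2@atoms$nH), sum(g@atoms$nH))
    expect_equal(sort(table(g2@atoms$symbol)), sort(table(g@atoms$symbol)))
  }
})

test_that("drug and pair tables round-trip; unknown ids are all named", {
  dir <- withr::local_tempdir()
  drugs <- makeDrugSet(c("d1", "d2", "d3"), c("CCO", "CCN", "CC(=O)O"))
  writeDrugTable(drugs, file.path(dir, "drugs.tsv"))
  back <- readDrugTable(file.path(dir, "drugs.tsv"))
  expect_identical(back@ids, drugs@ids)
  expect_identical(back@smiles, drugs@smiles)

  set.seed(3)
  pairs <- data.frame(
    drug_a = sample(drugs@ids, 100, replace = TRUE),
    drug_b = sample(drugs@ids, 100, replace = TRUE),
    label = sample(0:1, 100, replace = TRUE))
  writePairTable(pairs, file.path(dir, "pairs.tsv"))
  back <- readPairTable(file.path(dir, "pairs.tsv"), drugs)
  expect_identical(back$label, pairs$label)
  expect_identical(back$drug_a, pairs$drug_a)

  bad <- rbind(pairs, data.frame(drug_a = "DX", drug_b = "d1", label = 1L))
  writePairTable(bad, file.path(dir, "bad.tsv"))
  expect_error(readPairTable(file.path(dir, "bad.tsv"), drugs), "DX")

  preds <- data.frame(drug_a = pairs$drug_a, drug_b = pairs$drug_b,
                      probability = runif(100))
  writePredictions(preds, file.path(dir, "pred.tsv"))
  got <- utils::read.delim(file.path(dir, "pred.tsv"))
  expect_equal(got$probability, round(preds$probability, 6),
               tolerance = 1e-12)
})

test_that("duplicate drug ids are rejected", {
  expect_error(makeDrugSet(c("a", "a"), c("C", "CC")), "duplicate")
})
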