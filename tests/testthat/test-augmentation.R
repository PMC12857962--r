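test_that("importance scores order atoms by chemical salience", {
  benzeneC <- atomImportance(parseSmiles("c1ccccc1"), 1)
  tol <- parseSmiles("Cc1ccccc1")
  methylC <- atomImportance(tol, 1)
  expect_gte(benzeneC, methylC)

  ## isolated carbon: every component at its floor
  expect_equal(atomImportance(parseSmiles("C"), 1), 0)

  ## carboxyl oxygen beats a plain chain carbon
  g <- parseSmiles("CCCC(=O)O")
  expect_gt(atomImportance(g, 6), atomImportance(g, 2))
  expect_true(all(atomImportance(g) >= 0 & atomImportance(g) <= 1))
})

test_that("atom masking respects ratio, threshold and topology", {
  cfg <- runConfig()
  g <- parseSmiles(paste(rep("C", 20), collapse = ""))  # 20-atom chain
  set.seed(31)
  v <- atomMask(g, cfg)
  expect_equal(length(v$provenance$masked), 3L)  # floor(0.15 * 20)
  expect_true(all(atomImportance(g, v$provenance$masked) <
                  cfg$importance_threshold))
  expect_equal(numAtoms(v$view), numAtoms(g))  # token mode keeps n
  expect_true(all(v$view@maskFlags[v$provenance$masked]))

  cfg0 <- runConfig(mask_ratio = 0)
  v0 <- atomMask(g, cfg0)
  expect_identical(v0$view@maskFlags, g@maskFlags)
  expect_length(v0$provenance$masked, 0)
})

test_that("bond perturbation samples only valence-valid orders", {
  ## ethane: all three orders keep both carbons within valence 4
  g <- parseSmiles("CC")
  expect_setequal(validBondOrders(g, 1), c(1, 2, 3))
  ## the C-O bond of a carboxyl O-H: oxygen allows at most a double bond
  g2 <- parseSmiles("CO")
  expect_setequal(validBondOrders(g2, 1), c(1, 2))

  cfg0 <- runConfig(perturb_ratio = 0)
  v0 <- bondPerturb(g, cfg0)
  expect_identical(v0$view@bonds$order, g@bonds$order)

  ## validity audit over many random molecules
  set.seed(32)
  cfg <- runConfig()
  for (s in randomMolecules(60, seed = 32)) {
    gg <- parseSmiles(s)
    if (numBonds(gg) == 0) next
    v <- bondPerturb(gg, cfg)
    expect_length(graphDDI:::valenceViolations(v$view), 0)
    expect_true(validObject(v$view))
  }
})

test_that("subgraph sampling returns connected induced subgraphs of the right size", {
  set.seed(33)
  cfg <- runConfig()
  ## ratio 0.75 on an 8-atom molecule keeps ceiling(6) = 6 atoms
  g <- parseSmiles("CCCCCCCC")
  v <- subgraphSample(g, cfg)
  expect_equal(numAtoms(v$view), 6L)
  comp <- graphDDI:::graphComponents(v$view)
  expect_length(comp, 1)

  ## ratio 1 keeps the whole connected component
  v1 <- subgraphSample(g, runConfig(sample_ratio = 1))
  expect_equal(numAtoms(v1$view), 8L)

  ## induced property: kept-atom bonds survive, across random molecules
  for (s in randomMolecules(25, seed = 33)) {
    gg <- parseSmiles(s)
    v <- subgraphSample(gg, cfg)
    kept <- v$provenance$kept
    nBondsAmongKept <- sum(gg@bonds$a %in% kept & gg@bonds$b %in% kept)
    expect_equal(numBonds(v$view), nBondsAmongKept)
    expect_length(graphDDI:::graphComponents(v$view), 1)
  }
})

test_that("murcko scaffolds keep rings and linkers, drop side chains", {
  expect_length(murckoScaffold(parseSmiles("CCCC")), 0)  # acyclic
  expect_equal(sort(murckoScaffold(parseSmiles("c1ccccc1"))), 1:6)
  tol <- parseSmiles("Cc1ccccc1")
  expect_equal(sort(murckoScaffold(tol)), 2:7)
  ## biphenyl-type: both rings plus the connecting bond atoms
  bp <- parseSmiles("c1ccccc1Cc1ccccc1")
  expect_equal(length(murckoScaffold(bp)), 13)
})

test_that("scaffold hopping preserves side chains and validity", {
  drugs <- makeDrugSet(
    c("tol", "pyr", "clb"),
    c("Cc1ccccc1", "Cc1ccncc1", "CCc1ccccc1"))
  pool <- buildScaffoldPool(drugs)
  expect_length(pool, 3)

  cfg <- runConfig(hop_probability = 1)
  tol <- parseSmiles("Cc1ccccc1")
  hops <- 0
  set.seed(34)
  for (i in 1:20) {
    v <- scaffoldHop(tol, cfg, pool)
    if (isTRUE(v$provenance$hopped)) {
      hops <- hops + 1
      expect_equal(numAtoms(v$view), 7L)  # 6-ring + methyl
      expect_length(graphDDI:::valenceViolations(v$view), 0)
      ## side chain atom count conserved
      sc <- murckoScaffold(v$view)
      expect_equal(numAtoms(v$view) - length(sc), 1L)
    }
  }
  expect_gt(hops, 0)

  ## probability 0 is identity; acyclic molecules are identity
  v0 <- scaffoldHop(tol, runConfig(hop_probability = 0), pool)
  expect_false(isTRUE(v0$provenance$hopped))
  va <- scaffoldHop(parseSmiles("CCCC"), cfg, pool)
  expect_false(isTRUE(va$provenance$hopped))
})

test_that("ensemble draws follow the configured operator weights", {
  set.seed(35)
  g <- parseSmiles("Cc1ccc(N)cc1")
  cfg1 <- runConfig(ensemble_weights = c(1, 0, 0, 0))
  vs <- makeViews(g, cfg1)
  expect_equal(vs[[1]]$operator, "atom_mask")
  expect_equal(vs[[2]]$operator, "atom_mask")

  ## frequencies at equal weights stay within 3 sigma of the mean
  nDraw <- 1200
  ops <- character(nDraw)
  cfgE <- runConfig()
  for (i in seq_len(nDraw)) ops[i] <- makeViews(g, cfgE)[[1]]$operator
  counts <- table(factor(ops, levels = c("atom_mask", "bond_perturb",
                                         "subgraph_sample", "scaffold_hop")))
  expected <- nDraw / 4
  sigma <- sqrt(nDraw * 0.25 * 0.75)
  expect_true(all(abs(counts - expected) < 3 * sigma))
})

test_that("views are reproducible under a fixed seed and differ across seeds", {
  g <- parseSmiles("CC(=O)Oc1ccccc1C(=O)O")
  cfg <- runConfig()
  set.seed(40); a1 <- makeViews(g, cfg)
  set.seed(40); a2 <- makeViews(g, cfg)
  expect_identical(lapply(a1, `[[`, "provenance"),
                   lapply(a2, `[[`, "provenance"))
  set.seed(41); b <- makeViews(g, cfg)
  same <- identical(lapply(a1, `[[`, "provenance"),
                    lapply(b, `[[`, "provenance")) &&
    identical(vapply(a1, `[[`, "", "operator"),
              vapply(b, `[[`, "", "operator"))
  expect_false(same)
})
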