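## Chemically-constrained augmentation: four operators that each emit a
## valence-valid view of a molecule, plus their weighted ensemble. All
## operators are identity at ratio/probability zero and draw from R's
## global RNG (seed with set.seed for reproducibility).

#' Chemical importance of an atom
#'
#' Deterministic score in [0,1]:
#' 0.4 * in-ring + 0.3 * heteroatom + 0.2 * functional-group member +
#' 0.1 * min(degree, 4)/4. Ring members, heteroatoms and functional
#' groups score high and are protected from masking; peripheral carbons
#' score low.
#'
#' @param graph a \linkS4class{MolecularGraph}.
#' @param atom atom index (1-based); omit for all atoms.
#' @return numeric score(s).
#' @export
atomImportance <- function(graph, atom = NULL) {
  atoms <- graph@atoms
  fg <- functionalGroups(graph)
  fgMember <- rep(FALSE, nrow(atoms))
  for (idx in fg$atoms) fgMember[idx] <- TRUE
  s <- 0.4 * as.numeric(atoms$inRing) +
    0.3 * as.numeric(atoms$symbol != "C") +
    0.2 * as.numeric(fgMember) +
    0.1 * pmin(atoms$degree, 4) / 4
  if (is.null(atom)) s else s[atom]
}

.view <- function(graph, operator, provenance) {
  structure(list(view = graph, operator = operator, provenance = provenance),
            class = "AugmentedView")
}

#' Atom masking augmentation
#'
#' Masks floor(mask_ratio * n) atoms drawn from the candidates whose
#' importance is below the threshold (all of them if fewer). In the
#' default \code{token} mode masked atoms keep their topology but their
#' features are replaced by a learned mask embedding downstream; in
#' \code{delete} mode they are removed from the graph.
#'
#' @param graph a \linkS4class{MolecularGraph}.
#' @param config a \code{\link{runConfig}} (keys mask_ratio,
#'   importance_threshold, mask_mode).
#' @return an AugmentedView (list: view, operator, provenance).
#' @export
atomMask <- function(graph, config = runConfig()) {
  n <- numAtoms(graph)
  nMask <- floor(config$mask_ratio * n)
  cand <- which(atomImportance(graph) < config$importance_threshold)
  if (nMask == 0 || length(cand) == 0) {
    return(.view(graph, "atom_mask", list(masked = integer(0))))
  }
  chosen <- if (length(cand) <= nMask) cand else
    sort(sample(cand, nMask))
  if (config$mask_mode == "delete") {
    keep <- setdiff(seq_len(n), chosen)
    if (length(keep) == 0) {
      return(.view(graph, "atom_mask", list(masked = integer(0))))
    }
    out <- inducedSubgraph(graph, keep)
  } else {
    out <- graph
    out@maskFlags[chosen] <- TRUE
  }
  .view(out, "atom_mask", list(masked = chosen))
}

#' Bond orders that keep both endpoints within their valence
#'
#' Enumerates orders {1,2,3} for a bond, revalidating the effective
#' bond sums of both endpoints (implicit hydrogens shrink to absorb
#' increases). Aromatic bonds are not re-typed.
#'
#' @param graph a \linkS4class{MolecularGraph}.
#' @param bondIndex index into the bond table.
#' @return numeric vector of valid orders (includes the current one).
#' @export
validBondOrders <- function(graph, bondIndex) {
  bonds <- graph@bonds
  if (bonds$order[bondIndex] == 1.5) return(1.5)
  ok <- numeric(0)
  for (ord in c(1, 2, 3)) {
    b2 <- bonds
    b2$order[bondIndex] <- ord
    s <- effectiveBondSums(graph@atoms, b2)
    ends <- c(bonds$a[bondIndex], bonds$b[bondIndex])
    fits <- all(vapply(ends, function(i) {
      s[i] <= maxValence(graph@atoms$symbol[i], graph@atoms$charge[i]) + 1e-9
    }, TRUE))
    if (fits) ok <- c(ok, ord)
  }
  ok
}

#' Bond perturbation augmentation
#'
#' Re-types floor(perturb_ratio * m) non-aromatic bonds, each sampled
#' uniformly from the orders valid for both endpoints. Bonds with no
#' alternative order are left unchanged. The result is revalidated.
#'
#' @inheritParams atomMask
#' @export
bondPerturb <- function(graph, config = runConfig()) {
  m <- numBonds(graph)
  nPerturb <- floor(config$perturb_ratio * m)
  cand <- which(graph@bonds$order != 1.5)
  if (nPerturb == 0 || length(cand) == 0) {
    return(.view(graph, "bond_perturb", list(changed = integer(0))))
  }
  chosen <- if (length(cand) <= nPerturb) cand else
    sort(sample(cand, nPerturb))
  atoms <- graph@atoms
  bonds <- graph@bonds
  changed <- integer(0)
  ## each re-typing is validated against the bond table as already
  ## perturbed, so two changes sharing an endpoint cannot jointly
  ## overshoot its valence
  validNow <- function(k) {
    ok <- numeric(0)
    for (ord in c(1, 2, 3)) {
      b2 <- bonds
      b2$order[k] <- ord
      s <- effectiveBondSums(atoms, b2)
      ends <- c(bonds$a[k], bonds$b[k])
      fits <- all(vapply(ends, function(i) {
        s[i] <= maxValence(atoms$symbol[i], atoms$charge[i]) + 1e-9
      }, TRUE))
      if (fits) ok <- c(ok, ord)
    }
    ok
  }
  for (k in chosen) {
    opts <- setdiff(validNow(k), bonds$order[k])
    if (length(opts) == 0) next
    newOrd <- if (length(opts) == 1) opts else sample(opts, 1)
    bonds$order[k] <- newOrd
    changed <- c(changed, k)
  }
  if (length(changed) == 0) {
    return(.view(graph, "bond_perturb", list(changed = integer(0))))
  }
  ## recompute implicit H only at touched endpoints
  touched <- unique(c(bonds$a[changed], bonds$b[changed]))
  atoms$nH[touched] <- NA_integer_
  out <- buildGraph(atoms[, c("symbol", "charge", "aromatic", "nH")],
                    bonds[, c("a", "b", "order")],
                    explicitH = !is.na(atoms$nH),
                    maskFlags = graph@maskFlags)
  out@smiles <- writeSmiles(out)
  .view(out, "bond_perturb", list(changed = changed))
}

#' Subgraph sampling augmentation
#'
#' Seeds at a detected functional group (or a random atom when none
#' matches) and grows breadth-first until ceil(sample_ratio * n) atoms,
#' returning the connected induced subgraph, reindexed.
#'
#' @inheritParams atomMask
#' @export
subgraphSample <- function(graph, config = runConfig()) {
  n <- numAtoms(graph)
  target <- min(n, ceiling(config$sample_ratio * n))
  if (target >= n) {
    ## whole connected component containing the seed
    comp <- graphComponents(graph)
    if (length(comp) <= 1) {
      return(.view(graph, "subgraph_sample",
                   list(kept = seq_len(n), seed = NA)))
    }
  }
  fg <- functionalGroups(graph)
  seed <- if (nrow(fg) > 0) {
    fg$atoms[[sample(nrow(fg), 1)]]
  } else {
    sample(n, 1)
  }
  order <- bfsFrom(graph, seed)
  kept <- order[seq_len(min(target, length(order)))]
  out <- inducedSubgraph(graph, kept)
  .view(out, "subgraph_sample", list(kept = sort(kept), seed = seed))
}

#' Build a scaffold pool from a drug set
#'
#' Harvests the Murcko scaffold of every cyclic molecule: the induced
#' scaffold subgraph together with its attachment points (scaffold atoms
#' bonded to side chains), keyed by attachment-point count.
#'
#' @param drugs a \linkS4class{DrugSet}.
#' @return list of scaffold records (graph, attachment indices, source
#'   id).
#' @export
buildScaffoldPool <- function(drugs) {
  pool <- list()
  for (i in seq_along(drugs@ids)) {
    g <- drugs@graphs[[i]]
    sc <- murckoScaffold(g)
    if (length(sc) == 0) next
    ap <- scaffoldAttachmentPoints(g, sc)
    sub <- inducedSubgraph(g, sc)
    apLocal <- match(ap, sort(sc))
    pool[[length(pool) + 1L]] <- list(graph = sub, attach = apLocal,
                                      nAttach = length(apLocal),
                                      source = drugs@ids[i])
  }
  pool
}

#' Scaffold hopping augmentation
#'
#' With probability hop_probability, replaces the molecule's Murcko
#' scaffold with a pool scaffold that has the same number of attachment
#' points, reattaching side chains at the matched points. Acyclic
#' molecules, an empty pool, or a chemically invalid reattachment give
#' the identity view.
#'
#' @inheritParams atomMask
#' @param pool scaffold pool from \code{\link{buildScaffoldPool}}.
#' @export
scaffoldHop <- function(graph, config = runConfig(), pool = list()) {
  idview <- .view(graph, "scaffold_hop", list(hopped = FALSE))
  if (stats::runif(1) >= config$hop_probability) return(idview)
  sc <- murckoScaffold(graph)
  if (length(sc) == 0 || length(pool) == 0) return(idview)
  ap <- scaffoldAttachmentPoints(graph, sc)
  cand <- Filter(function(p) p$nAttach == length(ap), pool)
  if (length(cand) == 0) return(idview)
  donor <- cand[[sample(length(cand), 1)]]

  ## side chains: everything outside the scaffold, bonds into it noted
  n <- numAtoms(graph)
  side <- setdiff(seq_len(n), sc)
  atoms <- graph@atoms
  bonds <- graph@bonds
  dAtoms <- donor$graph@atoms
  dBonds <- donor$graph@bonds
  nd <- nrow(dAtoms)
  ## new atom table: donor scaffold first, then side atoms
  sideMap <- integer(n)
  sideMap[side] <- nd + seq_along(side)
  newAtoms <- rbind(
    dAtoms[, c("symbol", "charge", "aromatic", "nH")],
    atoms[side, c("symbol", "charge", "aromatic", "nH")])
  keepB <- bonds$a %in% side & bonds$b %in% side
  newBonds <- data.frame(
    a = sideMap[bonds$a[keepB]], b = sideMap[bonds$b[keepB]],
    order = bonds$order[keepB])
  newBonds <- rbind(dBonds[, c("a", "b", "order")], newBonds)
  ## crossing bonds: attach at matched attachment points
  crossing <- which(xor(bonds$a %in% sc, bonds$b %in% sc))
  for (k in crossing) {
    scEnd <- if (bonds$a[k] %in% sc) bonds$a[k] else bonds$b[k]
    sideEnd <- if (bonds$a[k] %in% sc) bonds$b[k] else bonds$a[k]
    slot <- match(scEnd, ap)
    newBonds <- rbind(newBonds, data.frame(
      a = donor$attach[slot], b = sideMap[sideEnd], order = bonds$order[k]))
  }
  newAtoms$nH <- NA_integer_
  out <- tryCatch({
    g <- buildGraph(newAtoms, newBonds,
                    explicitH = rep(FALSE, nrow(newAtoms)))
    g@smiles <- writeSmiles(g)
    g
  }, error = function(e) NULL)
  if (is.null(out)) return(idview)
  .view(out, "scaffold_hop",
        list(hopped = TRUE, donor = donor$source,
             side_atoms = length(side)))
}

#' Draw two augmented views for contrastive learning
#'
#' Each view applies one operator sampled by the ensemble weights
#' (atom_mask, bond_perturb, subgraph_sample, scaffold_hop), drawn
#' independently for the two views.
#'
#' @inheritParams scaffoldHop
#' @return list of two AugmentedViews.
#' @export
makeViews <- function(graph, config = runConfig(), pool = list()) {
  ops <- c("atom_mask", "bond_perturb", "subgraph_sample", "scaffold_hop")
  w <- config$ensemble_weights
  draw <- function() {
    op <- sample(ops, 1, prob = w)
    switch(op,
           atom_mask = atomMask(graph, config),
           bond_perturb = bondPerturb(graph, config),
           subgraph_sample = subgraphSample(graph, config),
           scaffold_hop = scaffoldHop(graph, config, pool))
  }
  list(draw(), draw())
}
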