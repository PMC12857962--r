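## Structural utilities over MolecularGraph: connectivity, functional
## group detection, and Murcko scaffolds. Functional groups are matched
## by explicit element/bond-order patterns, the substructure vocabulary
## the augmentation and the synthetic labeling rule share.

molIgraph <- function(graph) {
  n <- numAtoms(graph)
  el <- cbind(graph@bonds$a, graph@bonds$b)
  ig <- igraph::graph_from_edgelist(el, directed = FALSE)
  if (igraph::vcount(ig) < n) {
    ig <- igraph::add_vertices(ig, n - igraph::vcount(ig))
  }
  ig
}

#' Connected components as a list of atom index vectors
#' @noRd
graphComponents <- function(graph) {
  if (numAtoms(graph) == 0) return(list())
  comp <- igraph::components(molIgraph(graph))
  split(seq_len(numAtoms(graph)), comp$membership)
}

neighborsOf <- function(graph, i) {
  b <- graph@bonds
  c(b$b[b$a == i], b$a[b$b == i])
}

bondBetween <- function(graph, i, j) {
  b <- graph@bonds
  k <- which((b$a == i & b$b == j) | (b$a == j & b$b == i))
  if (length(k) == 0) NA_integer_ else k[1]
}

#' Detect functional groups in a molecular graph
#'
#' Matches a fixed pattern table by explicit subgraph search on element
#' symbols and bond orders: carboxyl (C(=O)OH / C(=O)O-), amine
#' (non-aromatic N not adjacent to a carbonyl carbon), hydroxyl (C-OH
#' outside carboxyls), carbonyl (C=O outside carboxyls), sulfonyl
#' (S(=O)(=O)), halogen on carbon, and aromatic rings (each connected
#' aromatic system is one match).
#'
#' @param graph a \linkS4class{MolecularGraph}.
#' @return a data.frame with columns \code{type} and \code{atoms}
#'   (list-column of atom index vectors), zero rows when nothing
#'   matches.
#' @export
functionalGroups <- function(graph) {
  atoms <- graph@atoms
  bonds <- graph@bonds
  n <- nrow(atoms)
  out <- list()
  push <- function(type, idx) {
    out[[length(out) + 1L]] <<- list(type = type, atoms = sort(unique(idx)))
  }
  if (n == 0) {
    return(data.frame(type = character(0),
                      atoms = I(list())))
  }

  dblO <- function(i) {
    ks <- which((bonds$a == i | bonds$b == i) & bonds$order == 2)
    js <- ifelse(bonds$a[ks] == i, bonds$b[ks], bonds$a[ks])
    js[atoms$symbol[js] == "O"]
  }
  sglO <- function(i) {
    ks <- which((bonds$a == i | bonds$b == i) & bonds$order == 1)
    js <- ifelse(bonds$a[ks] == i, bonds$b[ks], bonds$a[ks])
    js[atoms$symbol[js] == "O"]
  }

  carboxylC <- integer(0)
  carboxylAtoms <- integer(0)
  for (i in which(atoms$symbol == "C" & !atoms$aromatic)) {
    do <- dblO(i)
    so <- sglO(i)
    ## the single-bonded O must be terminal-ish (hydroxyl or anion)
    so <- so[atoms$nH[so] > 0 | atoms$charge[so] < 0 |
             atoms$degree[so] == 1]
    if (length(do) >= 1 && length(so) >= 1) {
      push("carboxyl", c(i, do[1], so[1]))
      carboxylC <- c(carboxylC, i)
      carboxylAtoms <- c(carboxylAtoms, i, do[1], so[1])
    }
  }

  ## carbonyl: C=O not already claimed by a carboxyl
  for (i in setdiff(which(atoms$symbol == "C"), carboxylC)) {
    do <- dblO(i)
    if (length(do) >= 1) push("carbonyl", c(i, do[1]))
  }

  ## sulfonyl: S with two double-bonded O
  for (i in which(atoms$symbol == "S")) {
    do <- dblO(i)
    if (length(do) >= 2) push("sulfonyl", c(i, do[1:2]))
  }

  ## amine: non-aromatic N, positive-charge-free, not bonded to a
  ## carbonyl/carboxyl/sulfonyl-type carbon or sulfur (excludes amides)
  for (i in which(atoms$symbol == "N" & !atoms$aromatic &
                  atoms$charge == 0)) {
    nb <- neighborsOf(graph, i)
    amide <- any(vapply(nb, function(j) {
      atoms$symbol[j] %in% c("C", "S") && length(dblO(j)) > 0
    }, TRUE))
    if (!amide) push("amine", i)
  }

  ## hydroxyl: O-H on carbon, outside carboxyls
  for (i in which(atoms$symbol == "O" & atoms$nH > 0 & !atoms$aromatic)) {
    if (i %in% carboxylAtoms) next
    nb <- neighborsOf(graph, i)
    if (any(atoms$symbol[nb] == "C")) push("hydroxyl", i)
  }

  ## halogen bonded to carbon
  for (i in which(atoms$symbol %in% .HALOGENS)) {
    nb <- neighborsOf(graph, i)
    cs <- nb[atoms$symbol[nb] == "C"]
    if (length(cs) > 0) push("halogen", c(i, cs[1]))
  }

  ## aromatic systems: connected components of the aromatic subgraph
  arom <- which(atoms$aromatic)
  if (length(arom) > 0) {
    sub <- igraph::induced_subgraph(molIgraph(graph), arom)
    comp <- igraph::components(sub)
    for (cid in seq_len(comp$no)) {
      push("aromatic_ring", arom[comp$membership == cid])
    }
  }

  if (length(out) == 0) {
    return(data.frame(type = character(0), atoms = I(list())))
  }
  data.frame(type = vapply(out, `[[`, "", "type"),
             atoms = I(lapply(out, `[[`, "atoms")))
}

#' Atom indices of the Murcko scaffold (rings plus linkers)
#'
#' Obtained by iteratively pruning terminal (degree-1) atoms until none
#' remain; what survives are the ring systems and the linker atoms
#' connecting them. Acyclic molecules have an empty scaffold.
#'
#' @param graph a \linkS4class{MolecularGraph}.
#' @return integer vector of scaffold atom indices (possibly empty).
#' @export
murckoScaffold <- function(graph) {
  n <- numAtoms(graph)
  if (n == 0 || numBonds(graph) == 0) return(integer(0))
  keep <- rep(TRUE, n)
  deg <- graph@atoms$degree
  repeat {
    term <- which(keep & deg <= 1)
    if (length(term) == 0) break
    for (i in term) {
      keep[i] <- FALSE
      for (j in neighborsOf(graph, i)) if (keep[j]) deg[j] <- deg[j] - 1
      deg[i] <- 0
    }
  }
  which(keep)
}

#' Scaffold attachment points: scaffold atoms bonded to side-chain atoms
#' @noRd
scaffoldAttachmentPoints <- function(graph, scaffold = murckoScaffold(graph)) {
  if (length(scaffold) == 0) return(integer(0))
  ap <- integer(0)
  for (i in scaffold) {
    nb <- neighborsOf(graph, i)
    if (any(!(nb %in% scaffold))) ap <- c(ap, i)
  }
  sort(unique(ap))
}

#' Induced subgraph on a set of atoms, reindexed from 1
#' @noRd
inducedSubgraph <- function(graph, atomsKeep) {
  atomsKeep <- sort(unique(as.integer(atomsKeep)))
  remap <- match(seq_len(numAtoms(graph)), atomsKeep)
  atomDf <- graph@atoms[atomsKeep, , drop = FALSE]
  rownames(atomDf) <- NULL
  b <- graph@bonds
  keepB <- b$a %in% atomsKeep & b$b %in% atomsKeep
  bondDf <- data.frame(a = remap[b$a[keepB]], b = remap[b$b[keepB]],
                       order = b$order[keepB])
  ## terminal aromatic fragments lose aromaticity in rebuild; buildGraph
  ## re-perceives rings and re-derives nH for consistency
  atomDf$nH <- NA_integer_
  atomDf <- atomDf[, c("symbol", "charge", "aromatic", "nH")]
  g <- buildGraph(atomDf, bondDf, smiles = "",
                  explicitH = rep(FALSE, nrow(atomDf)),
                  maskFlags = graph@maskFlags[atomsKeep])
  g@smiles <- writeSmiles(g)
  g
}

#' Breadth-first order of atoms from a seed set (within one component)
#' @noRd
bfsFrom <- function(graph, seeds) {
  n <- numAtoms(graph)
  seen <- rep(FALSE, n)
  order <- integer(0)
  queue <- as.integer(seeds)
  seen[queue] <- TRUE
  while (length(queue) > 0) {
    i <- queue[1]
    queue <- queue[-1]
    order <- c(order, i)
    nb <- neighborsOf(graph, i)
    nb <- nb[!seen[nb]]
    seen[nb] <- TRUE
    queue <- c(queue, sort(nb))
  }
  order
}
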