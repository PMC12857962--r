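## Atom and bond feature schemas. The default (version 1) schema is the
## minimal descriptor set common to graph-based DDI baselines:
## element one-hot over {C,N,O,S,P,F,Cl,Br,I,other} + degree one-hot
## (0-5) + formal charge one-hot (-2..+2) + aromatic flag + implicit-H
## one-hot (0-4) per atom; bond order one-hot {single,double,triple,
## aromatic} + in-ring flag per bond.

.SCHEMA_ELEMENTS <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "other")

#' The default feature schema
#'
#' @return a list describing the atom/bond feature layout:
#'   \code{d_atom} (27), \code{d_bond} (5), element vocabulary, and a
#'   \code{version} tag. Featurization is deterministic for a fixed
#'   schema version.
#' @export
featureSchema <- function() {
  list(version = 1L,
       elements = .SCHEMA_ELEMENTS,
       d_atom = length(.SCHEMA_ELEMENTS) + 6L + 5L + 1L + 5L,
       d_bond = 4L + 1L)
}

oneHot <- function(value, levels) {
  v <- numeric(length(levels))
  i <- match(value, levels)
  if (is.na(i)) i <- length(levels)  # reserved last slot
  v[i] <- 1
  v
}

#' Populate atom and bond feature matrices
#'
#' Fills \code{atomFeatures} (n x d_atom) and \code{bondFeatures}
#' (m x d_bond) per the schema. Elements outside the vocabulary map to
#' the reserved \code{other} slot. A pure function of (graph, schema):
#' identical inputs give bit-identical matrices.
#'
#' @param graph a parsed \linkS4class{MolecularGraph}.
#' @param schema a schema from \code{\link{featureSchema}}.
#' @return the graph with feature slots populated.
#' @export
featurize <- function(graph, schema = featureSchema()) {
  atoms <- graph@atoms
  n <- nrow(atoms)
  Xv <- matrix(0, n, schema$d_atom)
  for (i in seq_len(n)) {
    Xv[i, ] <- c(
      oneHot(atoms$symbol[i], schema$elements),
      oneHot(min(atoms$degree[i], 5L), 0:5),
      oneHot(max(-2L, min(2L, atoms$charge[i])), -2:2),
      as.numeric(atoms$aromatic[i]),
      oneHot(min(atoms$nH[i], 4L), 0:4)
    )
  }
  bonds <- graph@bonds
  m <- nrow(bonds)
  Xe <- matrix(0, m, schema$d_bond)
  for (k in seq_len(m)) {
    ord <- bonds$order[k]
    Xe[k, ] <- c(
      as.numeric(ord == 1), as.numeric(ord == 2),
      as.numeric(ord == 3), as.numeric(ord == 1.5),
      as.numeric(bonds$inRing[k])
    )
  }
  graph@atomFeatures <- Xv
  graph@bondFeatures <- Xe
  graph
}
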