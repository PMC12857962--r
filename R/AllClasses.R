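#' @import methods
NULL

#' MolecularGraph: a featurized heavy-atom molecular graph
#'
#' Represents one molecule as G = (V, E, Xv, Xe): an atom table, a bond
#' table, per-atom and per-bond feature matrices and a binary adjacency
#' matrix. Hydrogens are implicit (stored as a per-atom count, never as
#' graph nodes). Atom indices follow SMILES reading order, 1-based in R.
#'
#' @slot atoms data.frame with columns \code{symbol}, \code{charge},
#'   \code{aromatic}, \code{nH} (implicit hydrogens), \code{degree},
#'   \code{inRing}.
#' @slot bonds data.frame with columns \code{a}, \code{b} (endpoint
#'   indices), \code{order} (1, 2, 3 or 1.5 for aromatic),
#'   \code{aromatic}, \code{inRing}.
#' @slot adjacency n x n binary symmetric matrix with zero diagonal.
#' @slot atomFeatures n x d_atom numeric matrix (filled by
#'   \code{\link{featurize}}).
#' @slot bondFeatures m x d_bond numeric matrix.
#' @slot smiles the source SMILES string.
#' @slot maskFlags per-atom logical, set by the atom-masking
#'   augmentation; masked atoms are embedded with a learned mask token.
#'
#' @seealso \code{\link{parseSmiles}}, \code{\link{featurize}},
#'   \code{\link{chemicalDistance}}
#' @export
setClass("MolecularGraph",
  representation(
    atoms = "data.frame",
    bonds = "data.frame",
    adjacency = "matrix",
    atomFeatures = "matrix",
    bondFeatures = "matrix",
    smiles = "character",
    maskFlags = "logical"
  )
)

setValidity("MolecularGraph", function(object) {
  n <- nrow(object@atoms)
  m <- nrow(object@bonds)
  msg <- character(0)
  A <- object@adjacency
  if (!all(dim(A) == c(n, n))) {
    msg <- c(msg, "adjacency dimension does not match atom count")
  } else {
    if (any(A != t(A))) msg <- c(msg, "adjacency not symmetric")
    if (n > 0 && any(diag(A) != 0)) msg <- c(msg, "adjacency diagonal not zero")
  }
  if (m > 0 && (any(object@bonds$a > n) || any(object@bonds$b > n) ||
                any(object@bonds$a < 1) || any(object@bonds$b < 1))) {
    msg <- c(msg, "bond endpoint index out of range")
  }
  if (nrow(object@atomFeatures) > 0 && nrow(object@atomFeatures) != n) {
    msg <- c(msg, "atomFeatures row count != atom count")
  }
  if (nrow(object@bondFeatures) > 0 && nrow(object@bondFeatures) != m) {
    msg <- c(msg, "bondFeatures row count != bond count")
  }
  if (length(object@maskFlags) != n) {
    msg <- c(msg, "maskFlags length != atom count")
  }
  viol <- valenceViolations(object)
  if (length(viol) > 0) {
    msg <- c(msg, sprintf("valence exceeded at atom(s) %s",
                          paste(viol, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' DrugSet: an ordered collection of identified molecules
#'
#' Maps unique drug identifiers to SMILES strings and their parsed
#' \linkS4class{MolecularGraph}s. This is the in-memory form of the
#' on-disk drug table (TSV with columns \code{drug_id}, \code{smiles}).
#'
#' @slot ids character vector of unique drug identifiers.
#' @slot smiles character vector, parallel to \code{ids}.
#' @slot graphs list of \linkS4class{MolecularGraph}, parallel to
#'   \code{ids}.
#' @export
setClass("DrugSet",
  representation(ids = "character", smiles = "character", graphs = "list")
)

setValidity("DrugSet", function(object) {
  msg <- character(0)
  if (anyDuplicated(object@ids)) msg <- c(msg, "drug ids not unique")
  if (length(object@smiles) != length(object@ids) ||
      length(object@graphs) != length(object@ids)) {
    msg <- c(msg, "ids, smiles and graphs differ in length")
  }
  if (length(msg)) msg else TRUE
})

#' DDIModel: a trained (or initialized) interaction prediction model
#'
#' Holds the full parameter set of the graph transformer encoder,
#' sequence encoder, fusion block, projection head and prediction head,
#' together with the run configuration they were built under.
#'
#' @slot params named list of numeric parameter matrices.
#' @slot config run configuration list (see \code{\link{runConfig}}).
#' @slot vocab character vector: the SMILES token vocabulary of the
#'   sequence encoder.
#' @export
setClass("DDIModel",
  representation(params = "list", config = "list", vocab = "character")
)

#' @describeIn MolecularGraph-class number of atoms
#' @param x a \linkS4class{MolecularGraph}
#' @export
numAtoms <- function(x) nrow(x@atoms)

#' @describeIn MolecularGraph-class number of bonds
#' @export
numBonds <- function(x) nrow(x@bonds)

#' @rdname DrugSet-class
#' @param x a \linkS4class{DrugSet}
#' @export
drugIds <- function(x) x@ids

#' @rdname DrugSet-class
#' @param id a drug identifier
#' @export
getGraph <- function(x, id) {
  i <- match(id, x@ids)
  if (is.na(i)) stop("unknown drug id: ", id)
  x@graphs[[i]]
}

setMethod("show", "MolecularGraph", function(object) {
  cat(sprintf("MolecularGraph: %d atoms, %d bonds\n",
              numAtoms(object), numBonds(object)))
  cat("  smiles: ", object@smiles, "\n", sep = "")
  if (any(object@atoms$aromatic)) {
    cat(sprintf("  aromatic atoms: %d\n", sum(object@atoms$aromatic)))
  }
  if (any(object@maskFlags)) {
    cat(sprintf("  masked atoms: %d\n", sum(object@maskFlags)))
  }
})

setMethod("show", "DrugSet", function(object) {
  cat(sprintf("DrugSet with %d drugs\n", length(object@ids)))
  if (length(object@ids) > 0) {
    k <- min(3L, length(object@ids))
    for (i in seq_len(k)) {
      cat(sprintf("  %s: %s\n", object@ids[i], object@smiles[i]))
    }
    if (length(object@ids) > k) cat("  ...\n")
  }
})

setMethod("show", "DDIModel", function(object) {
  np <- sum(vapply(object@params, length, 1L))
  cat(sprintf("DDIModel: %d parameters in %d tensors\n",
              np, length(object@params)))
  cfg <- object@config
  cat(sprintf("  d_model=%d layers=%d heads=%d d_bert=%d\n",
              cfg$d_model, cfg$n_layers, cfg$n_heads, cfg$d_bert))
  on <- c(contrastive = cfg$use_contrastive, fusion = cfg$fusion_on,
          spatial = cfg$spatial_bias_on, hier_pool = cfg$use_hier_pool)
  cat("  switches on: ", paste(names(on)[unlist(on)], collapse = ", "),
      "\n", sep = "")
})
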