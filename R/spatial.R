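## Chemical-distance spatial encoding: the attention bias of the graph
## transformer is keyed on the minimum summed bond weight between two
## atoms. Unit weights give the topological shortest path (integer
## buckets); the bond_order_inverse scheme weighs each bond 1/order
## (aromatic order 1.5).

#' Chemical distance matrix of a molecule
#'
#' For every atom pair, the minimum over all connecting paths of the
#' summed bond weights. \code{unit} weights every bond 1 (topological
#' distance); \code{bond_order_inverse} weights a bond 1/order so that
#' multiple bonds count as "chemically closer". Disconnected pairs get
#' \code{Inf}. Computed with Dijkstra's algorithm from every source.
#'
#' @param graph a \linkS4class{MolecularGraph}.
#' @param scheme \code{"unit"} or \code{"bond_order_inverse"}.
#' @return a list with \code{dist} (n x n symmetric, zero diagonal, Inf
#'   for unreachable) and \code{scheme}.
#' @export
chemicalDistance <- function(graph, scheme = c("unit", "bond_order_inverse")) {
  scheme <- match.arg(scheme)
  n <- numAtoms(graph)
  bonds <- graph@bonds
  w <- if (scheme == "unit") rep(1, nrow(bonds)) else 1 / bonds$order
  ## adjacency lists with weights
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    a <- bonds$a[k]; b <- bonds$b[k]
    adj[[a]] <- rbind(adj[[a]], c(b, w[k]))
    adj[[b]] <- rbind(adj[[b]], c(a, w[k]))
  }
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    done <- rep(FALSE, n)
    repeat {
      cand <- which(!done & is.finite(dist))
      if (length(cand) == 0) break
      u <- cand[which.min(dist[cand])]
      done[u] <- TRUE
      for (r in seq_len(NROW(adj[[u]]))) {
        if (is.null(adj[[u]])) break
        v <- adj[[u]][r, 1]
        alt <- dist[u] + adj[[u]][r, 2]
        if (alt < dist[v]) dist[v] <- alt
      }
    }
    D[s, ] <- dist
  }
  list(dist = D, scheme = scheme)
}

#' Clip distances into embedding buckets
#'
#' Buckets are 1-based for R indexing: bucket 1 holds distance 0 (self),
#' bucket d+1 holds integer distance d, distances above \code{dMax}
#' share bucket \code{dMax + 1}... and unreachable pairs get the
#' dedicated final bucket \code{dMax + 2}. Non-integer weighted
#' distances are rounded to the nearest integer bucket.
#'
#' @param spatial output of \code{\link{chemicalDistance}}.
#' @param dMax largest individually-resolved distance (default 8).
#' @return n x n integer matrix of bucket indices in [1, dMax + 2].
#' @export
distanceBuckets <- function(spatial, dMax = 8L) {
  D <- spatial$dist
  B <- matrix(0L, nrow(D), ncol(D))
  finite <- is.finite(D)
  B[finite] <- pmin(as.integer(round(D[finite])), dMax) + 1L
  B[!finite] <- dMax + 2L
  B
}

#' Realize per-head bias matrices from the learned bucket table
#'
#' The embedding table has one learned scalar per (bucket, head); entry
#' S[h][i,j] = table[bucket(i,j), h]. During training this lookup is
#' done inside the attention op so gradient reaches the table; this
#' function is the standalone (inference/inspection) form.
#'
#' @param buckets n x n integer bucket matrix.
#' @param table (dMax + 2) x H numeric table.
#' @return list of H n x n bias matrices.
#' @export
spatialBias <- function(buckets, table) {
  if (max(buckets) > nrow(table)) {
    stop("internal error: bucket index exceeds bias table size")
  }
  lapply(seq_len(ncol(table)), function(h) {
    matrix(table[buckets, h], nrow(buckets), ncol(buckets))
  })
}
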