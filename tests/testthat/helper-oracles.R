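## Shared fixtures and independent oracles. Oracles are deliberately
## written as naive double loops / enumerations, independent of the
## package's vectorized implementations.

## a small panel of hand-checkable molecules
fixtureSmiles <- function() {
  c(ethanol = "CCO",
    benzene = "c1ccccc1",
    aceticAcid = "CC(=O)O",
    pyridine = "c1ccncc1",
    toluene = "Cc1ccccc1",
    ethylamine = "CCN",
    aspirinLike = "CC(=O)Oc1ccccc1C(=O)O",
    chlorobenzene = "Clc1ccccc1",
    sulfone = "CS(=O)(=O)C",
    naphthalene = "c1ccc2ccccc2c1")
}

randomMolecules <- function(n, seed = 1L) {
  set.seed(seed)
  cfgG <- generatorConfig(n_drugs = n, seed = seed)
  vapply(seq_len(n), function(i) generateMolecule(cfgG), "")
}

## all-pairs shortest paths by plain breadth-first search (unit weights)
bfsDistOracle <- function(graph) {
  n <- numAtoms(graph)
  A <- graph@adjacency
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    queue <- s
    while (length(queue) > 0) {
      u <- queue[1]
      queue <- queue[-1]
      for (v in which(A[u, ] == 1)) {
        if (dist[v] > dist[u] + 1) {
          dist[v] <- dist[u] + 1
          queue <- c(queue, v)
        }
      }
    }
    D[s, ] <- dist
  }
  D
}

## scalar double-loop position-aware attention for one head
attentionOracle <- function(X, Wq, Wk, Wv, S, biasInside = TRUE) {
  Q <- X %*% Wq
  K <- X %*% Wk
  V <- X %*% Wv
  n <- nrow(X)
  dk <- ncol(Q)
  out <- matrix(0, n, ncol(V))
  for (i in seq_len(n)) {
    z <- numeric(n)
    for (j in seq_len(n)) {
      qk <- sum(Q[i, ] * K[j, ])
      z[j] <- if (biasInside) (qk + S[i, j]) / sqrt(dk) else
        qk / sqrt(dk) + S[i, j]
    }
    a <- exp(z - max(z))
    a <- a / sum(a)
    for (j in seq_len(n)) out[i, ] <- out[i, ] + a[j] * V[j, ]
  }
  out
}

## AUC by exhaustive concordance count over positive-negative pairs
aucOracle <- function(scores, labels) {
  pos <- which(labels == 1)
  neg <- which(labels == 0)
  total <- 0
  for (i in pos) {
    for (j in neg) {
      total <- total + if (scores[i] > scores[j]) 1 else
        if (scores[i] == scores[j]) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

## step-interpolated average precision, naive cut-by-cut reference
apOracle <- function(scores, labels) {
  cuts <- sort(unique(scores), decreasing = TRUE)
  nP <- sum(labels == 1)
  prevRec <- 0
  ap <- 0
  for (ct in cuts) {
    sel <- scores >= ct
    tp <- sum(labels[sel] == 1)
    prec <- tp / sum(sel)
    rec <- tp / nP
    ap <- ap + prec * (rec - prevRec)
    prevRec <- rec
  }
  ap
}

## central-difference gradient of f(params) w.r.t. the named tensors
fdGrad <- function(f, params, which = base::names(params), eps = 1e-6) {
  out <- lapply(params[which], function(P) matrix(0, nrow(P), ncol(P)))
  for (nm in which) {
    P <- params[[nm]]
    for (i in seq_along(P)) {
      p1 <- params; p1[[nm]][i] <- p1[[nm]][i] + eps
      p2 <- params; p2[[nm]][i] <- p2[[nm]][i] - eps
      out[[nm]][i] <- (f(p1) - f(p2)) / (2 * eps)
    }
  }
  out
}

## tiny desk model configuration used across neural tests
tinyConfig <- function(...) {
  base <- list(d_model = 16L, n_layers = 1L, n_heads = 2L, d_bert = 8L,
               seq_layers = 1L, seq_heads = 2L, head_dims = c(32L, 16L),
               projection_dim = 8L, k2_cap = 4L, batch_size = 8L,
               hard_negative_k = 3L, dropout = 0)
  dots <- list(...)
  base[names(dots)] <- dots
  do.call(runConfig, base)
}

## encode a set of SMILES with a model, returning h_final values
encodeSmiles <- function(smiles, model) {
  drugs <- makeDrugSet(paste0("D", seq_along(smiles)), smiles)
  cache <- precomputeDrugs(drugs, model@config)
  tape <- graphDDI:::adTape()
  leaves <- graphDDI:::paramLeaves(tape, model@params)
  enc <- graphDDI:::encodeBatch(tape, leaves, cache, model@config,
                                training = FALSE)
  graphDDI:::adVal(enc$h_final)
}
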