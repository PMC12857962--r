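#' @title Fused segmented neural ops
#'
#' @description
#' Molecules in a batch have different atom counts, so node states are
#' stacked into a single (sum n_i) x d matrix and attention is
#' block-diagonal: each molecule attends only within itself. The ops
#' here fuse the per-molecule loop into one tape node each (forward and
#' analytic backward), which keeps the tape short and training fast.
#'
#' @name nn-ops
#' @keywords internal
NULL

## start/end row offsets for each segment
segOffsets <- function(sizes) {
  ends <- cumsum(sizes)
  list(starts = ends - sizes + 1L, ends = ends)
}

rowMaxs <- function(Z) {
  Z[cbind(seq_len(nrow(Z)), max.col(Z, ties.method = "first"))]
}

rowMaxs <- function(Z) {
  Z[cbind(seq_len(nrow(Z)), max.col(Z, ties.method = "first"))]
}

softmaxMat <- function(Z) {
  E <- exp(Z - rowMaxs(Z))
  E / rowSums(E)
}

#' Block-diagonal position-aware self-attention for one head.
#'
#' Computes, per molecule, softmax((Q K^T + S) / sqrt(dk)) V where S is
#' the spatial bias realized from a learned bucket table. `buckets` is a
#' list of n_i x n_i integer matrices (1-based bucket index); `biasCol`
#' is a (n_buckets x 1) node holding this head's column of the bias
#' table. Gradient flows to Q, K, V and to the bias table entries.
#' With `biasInsideScale = FALSE` the bias is added after the 1/sqrt(dk)
#' scaling instead of before it.
#'
#' @noRd
adBlockAttention <- function(Q, K, V, biasCol, buckets, sizes,
                             biasInsideScale = TRUE) {
  Qv <- adVal(Q); Kv <- adVal(K); Vv <- adVal(V)
  bc <- as.numeric(adVal(biasCol))
  dk <- ncol(Qv)
  sc <- 1 / sqrt(dk)
  off <- segOffsets(sizes)
  B <- length(sizes)
  out <- matrix(0, nrow(Qv), ncol(Vv))
  attn <- vector("list", B)
  for (b in seq_len(B)) {
    r <- off$starts[b]:off$ends[b]
    Qi <- Qv[r, , drop = FALSE]
    Ki <- Kv[r, , drop = FALSE]
    S <- matrix(bc[buckets[[b]]], sizes[b], sizes[b])
    Z <- if (biasInsideScale) (tcrossprod(Qi, Ki) + S) * sc
         else tcrossprod(Qi, Ki) * sc + S
    A <- softmaxMat(Z)
    attn[[b]] <- A
    out[r, ] <- A %*% Vv[r, , drop = FALSE]
  }
  node <- adPush(Q$tape, out, c(Q$id, K$id, V$id, biasCol$id), function(g) {
    dQ <- matrix(0, nrow(Qv), ncol(Qv))
    dK <- matrix(0, nrow(Kv), ncol(Kv))
    dV <- matrix(0, nrow(Vv), ncol(Vv))
    dTab <- numeric(length(bc))
    for (b in seq_len(B)) {
      r <- off$starts[b]:off$ends[b]
      A <- attn[[b]]
      gi <- g[r, , drop = FALSE]
      Vi <- Vv[r, , drop = FALSE]
      dV[r, ] <- crossprod(A, gi)
      dA <- tcrossprod(gi, Vi)
      dZ <- A * (dA - rowSums(dA * A))
      dS <- if (biasInsideScale) dZ * sc else dZ
      dZsc <- dZ * sc
      dQ[r, ] <- dZsc %*% Kv[r, , drop = FALSE]
      dK[r, ] <- crossprod(dZsc, Qv[r, , drop = FALSE])
      idx <- as.integer(buckets[[b]])
      acc <- rowsum(as.numeric(dS), group = idx)
      dTab[as.integer(rownames(acc))] <- dTab[as.integer(rownames(acc))] +
        as.numeric(acc)
    }
    list(dQ, dK, dV, matrix(dTab, ncol = 1L))
  })
  attr(node, "attn") <- attn
  node
}

#' Block cross-attention: graph atom states (queries) over SMILES token
#' states (keys/values), per molecule. Returns stacked attended rows
#' aligned with the query stacking.
#' @noRd
adBlockCrossAttention <- function(Qg, Tk, Tv, sizesN, sizesL) {
  Qv <- adVal(Qg); Kv <- adVal(Tk); Vv <- adVal(Tv)
  sc <- 1 / sqrt(ncol(Qv))
  offN <- segOffsets(sizesN)
  offL <- segOffsets(sizesL)
  B <- length(sizesN)
  out <- matrix(0, nrow(Qv), ncol(Vv))
  attn <- vector("list", B)
  for (b in seq_len(B)) {
    rn <- offN$starts[b]:offN$ends[b]
    rl <- offL$starts[b]:offL$ends[b]
    A <- softmaxMat(tcrossprod(Qv[rn, , drop = FALSE],
                               Kv[rl, , drop = FALSE]) * sc)
    attn[[b]] <- A
    out[rn, ] <- A %*% Vv[rl, , drop = FALSE]
  }
  node <- adPush(Qg$tape, out, c(Qg$id, Tk$id, Tv$id), function(g) {
    dQ <- matrix(0, nrow(Qv), ncol(Qv))
    dK <- matrix(0, nrow(Kv), ncol(Kv))
    dV <- matrix(0, nrow(Vv), ncol(Vv))
    for (b in seq_len(B)) {
      rn <- offN$starts[b]:offN$ends[b]
      rl <- offL$starts[b]:offL$ends[b]
      A <- attn[[b]]
      gi <- g[rn, , drop = FALSE]
      dV[rl, ] <- dV[rl, ] + crossprod(A, gi)
      dA <- tcrossprod(gi, Vv[rl, , drop = FALSE])
      dZ <- A * (dA - rowSums(dA * A))
      dQ[rn, ] <- dZ %*% Kv[rl, , drop = FALSE] * sc
      dK[rl, ] <- dK[rl, ] + crossprod(dZ, Qv[rn, , drop = FALSE]) * sc
    }
    list(dQ, dK, dV)
  })
  attr(node, "attn") <- attn
  node
}

#' Per-segment t(S) %*% Z: soft cluster aggregation (DiffPool).
#' S is stacked (sum n_i) x K assignments, Z stacked states; rows of the
#' result are stacked cluster states, sizesK[i] = clusters of molecule i
#' (columns 1..sizesK[i] of S are active for that molecule).
#' @noRd
adSegmentPool <- function(S, Z, sizesN, sizesK) {
  Sv <- adVal(S); Zv <- adVal(Z)
  offN <- segOffsets(sizesN)
  offK <- segOffsets(sizesK)
  B <- length(sizesN)
  out <- matrix(0, sum(sizesK), ncol(Zv))
  for (b in seq_len(B)) {
    rn <- offN$starts[b]:offN$ends[b]
    rk <- offK$starts[b]:offK$ends[b]
    Si <- Sv[rn, seq_len(sizesK[b]), drop = FALSE]
    out[rk, ] <- crossprod(Si, Zv[rn, , drop = FALSE])
  }
  adPush(S$tape, out, c(S$id, Z$id), function(g) {
    dS <- matrix(0, nrow(Sv), ncol(Sv))
    dZ <- matrix(0, nrow(Zv), ncol(Zv))
    for (b in seq_len(B)) {
      rn <- offN$starts[b]:offN$ends[b]
      rk <- offK$starts[b]:offK$ends[b]
      gk <- g[rk, , drop = FALSE]
      dS[rn, seq_len(sizesK[b])] <- tcrossprod(Zv[rn, , drop = FALSE], gk)
      dZ[rn, ] <- Sv[rn, seq_len(sizesK[b]), drop = FALSE] %*% gk
    }
    list(dS, dZ)
  })
}

#' Softmax within column segments (one score per stacked row).
#' @noRd
adSegmentSoftmax <- function(x, sizes) {
  X <- as.numeric(adVal(x))
  off <- segOffsets(sizes)
  out <- numeric(length(X))
  for (b in seq_along(sizes)) {
    r <- off$starts[b]:off$ends[b]
    e <- exp(X[r] - max(X[r]))
    out[r] <- e / sum(e)
  }
  adPush(x$tape, matrix(out, ncol = 1L), x$id, function(g) {
    gv <- as.numeric(g)
    dX <- numeric(length(X))
    for (b in seq_along(sizes)) {
      r <- off$starts[b]:off$ends[b]
      p <- out[r]
      dX[r] <- p * (gv[r] - sum(gv[r] * p))
    }
    list(matrix(dX, ncol = 1L))
  })
}

#' Gated sum per segment: out[b, ] = sum_k gate_k * V[k, ].
#' @noRd
adSegmentWeightedSum <- function(gate, V, sizes) {
  Gv <- as.numeric(adVal(gate)); Vv <- adVal(V)
  off <- segOffsets(sizes)
  B <- length(sizes)
  out <- matrix(0, B, ncol(Vv))
  for (b in seq_len(B)) {
    r <- off$starts[b]:off$ends[b]
    out[b, ] <- colSums(Vv[r, , drop = FALSE] * Gv[r])
  }
  adPush(gate$tape, out, c(gate$id, V$id), function(g) {
    dG <- numeric(length(Gv))
    dV <- matrix(0, nrow(Vv), ncol(Vv))
    for (b in seq_len(B)) {
      r <- off$starts[b]:off$ends[b]
      gb <- g[b, ]
      dG[r] <- as.numeric(Vv[r, , drop = FALSE] %*% gb)
      dV[r, ] <- rep(gb, each = length(r)) * Gv[r]
    }
    list(matrix(dG, ncol = 1L), dV)
  })
}

#' Mean of rows within each segment -> B x d matrix.
#' @noRd
adSegmentMean <- function(x, sizes) {
  X <- adVal(x)
  off <- segOffsets(sizes)
  B <- length(sizes)
  out <- matrix(0, B, ncol(X))
  for (b in seq_len(B)) {
    r <- off$starts[b]:off$ends[b]
    out[b, ] <- colMeans(X[r, , drop = FALSE])
  }
  adPush(x$tape, out, x$id, function(g) {
    dX <- matrix(0, nrow(X), ncol(X))
    for (b in seq_len(B)) {
      r <- off$starts[b]:off$ends[b]
      dX[r, ] <- rep(g[b, ] / sizes[b], each = length(r))
    }
    list(dX)
  })
}

#' DiffPool auxiliary losses (link prediction + assignment entropy),
#' fused per batch. Returns a 1x1 node. `adjs` is the list of (constant)
#' adjacency matrices. Off by default in training (weight 0).
#' @noRd
adDiffPoolAux <- function(S, adjs, sizesN, sizesK) {
  Sv <- adVal(S)
  off <- segOffsets(sizesN)
  B <- length(sizesN)
  lp <- 0; ent <- 0
  for (b in seq_len(B)) {
    r <- off$starts[b]:off$ends[b]
    Si <- Sv[r, seq_len(sizesK[b]), drop = FALSE]
    Rm <- adjs[[b]] - tcrossprod(Si)
    lp <- lp + sum(Rm^2) / (sizesN[b]^2)
    ent <- ent + sum(-Si * log(Si + 1e-12)) / sizesN[b]
  }
  val <- matrix((lp + ent) / B, 1L, 1L)
  adPush(S$tape, val, S$id, function(g) {
    gv <- as.numeric(g) / B
    dS <- matrix(0, nrow(Sv), ncol(Sv))
    for (b in seq_len(B)) {
      r <- off$starts[b]:off$ends[b]
      kc <- seq_len(sizesK[b])
      Si <- Sv[r, kc, drop = FALSE]
      Rm <- adjs[[b]] - tcrossprod(Si)
      dS[r, kc] <- gv * (-4 * (Rm %*% Si) / (sizesN[b]^2) +
                           (-log(Si + 1e-12) - 1) / sizesN[b])
    }
    list(dS)
  })
}

#' Row-wise softmax over a per-segment prefix of columns: rows of
#' molecule b are normalized over columns 1..sizesK[b]; remaining
#' columns are zero. Used for the DiffPool assignment with a
#' molecule-dependent cluster count.
#' @noRd
adRowSoftmaxVarCols <- function(x, sizesN, sizesK) {
  X <- adVal(x)
  off <- segOffsets(sizesN)
  P <- matrix(0, nrow(X), ncol(X))
  for (b in seq_along(sizesN)) {
    r <- off$starts[b]:off$ends[b]
    kc <- seq_len(sizesK[b])
    Z <- X[r, kc, drop = FALSE]
    E <- exp(Z - rowMaxs(Z))
    P[r, kc] <- E / rowSums(E)
  }
  adPush(x$tape, P, x$id, function(g) {
    dX <- matrix(0, nrow(X), ncol(X))
    for (b in seq_along(sizesN)) {
      r <- off$starts[b]:off$ends[b]
      kc <- seq_len(sizesK[b])
      Pb <- P[r, kc, drop = FALSE]
      gb <- g[r, kc, drop = FALSE]
      dX[r, kc] <- Pb * (gb - rowSums(gb * Pb))
    }
    list(dX)
  })
}

#' Per-segment multiplication by constant square matrices (message
#' passing with a fixed normalized adjacency): out rows of molecule b =
#' mats[[b]] %*% X rows of molecule b.
#' @noRd
adBlockConstMatmul <- function(mats, x, sizes) {
  X <- adVal(x)
  off <- segOffsets(sizes)
  out <- matrix(0, nrow(X), ncol(X))
  for (b in seq_along(sizes)) {
    r <- off$starts[b]:off$ends[b]
    out[r, ] <- mats[[b]] %*% X[r, , drop = FALSE]
  }
  adPush(x$tape, out, x$id, function(g) {
    dX <- matrix(0, nrow(X), ncol(X))
    for (b in seq_along(sizes)) {
      r <- off$starts[b]:off$ends[b]
      dX[r, ] <- crossprod(mats[[b]], g[r, , drop = FALSE])
    }
    list(dX)
  })
}

#' Fused affine map: X %*% W + bias row, one node
#' @noRd
adLinear <- function(x, W, bias) {
  X <- adVal(x); Wv <- adVal(W); bv <- as.numeric(adVal(bias))
  Y <- cpp_add_bias_inplace(X %*% Wv, bv)
  adPush(x$tape, Y, c(x$id, W$id, bias$id), function(g) {
    list(tcrossprod(g, Wv), crossprod(X, g), matrix(colSums(g), 1L))
  })
}

#' All attention heads of one layer in a single node.
#'
#' Q, K, V are stacked N x d_model; head h uses the column slice
#' ((h-1)*dk+1):(h*dk) and bias column h of the bucket table. The
#' output is the concatenation over heads (N x d_model), ready for the
#' output projection.
#' @noRd
adBlockMultiHead <- function(Q, K, V, biasTab, buckets, sizes, nHeads,
                             biasInsideScale = TRUE) {
  Qv <- adVal(Q); Kv <- adVal(K); Vv <- adVal(V)
  tab <- adVal(biasTab)
  d <- ncol(Qv)
  dk <- d %/% nHeads
  sc <- 1 / sqrt(dk)
  off <- segOffsets(sizes)
  B <- length(sizes)
  out <- matrix(0, nrow(Qv), d)
  attn <- vector("list", B * nHeads)
  for (b in seq_len(B)) {
    r <- off$starts[b]:off$ends[b]
    for (h in seq_len(nHeads)) {
      cols <- ((h - 1) * dk + 1):(h * dk)
      S <- matrix(tab[buckets[[b]], h], sizes[b], sizes[b])
      QK <- tcrossprod(Qv[r, cols, drop = FALSE], Kv[r, cols, drop = FALSE])
      Z <- if (biasInsideScale) (QK + S) * sc else QK * sc + S
      A <- softmaxMat(Z)
      attn[[(b - 1) * nHeads + h]] <- A
      out[r, cols] <- A %*% Vv[r, cols, drop = FALSE]
    }
  }
  adPush(Q$tape, out, c(Q$id, K$id, V$id, biasTab$id), function(g) {
    dQ <- matrix(0, nrow(Qv), d)
    dK <- matrix(0, nrow(Kv), d)
    dV <- matrix(0, nrow(Vv), d)
    dTab <- matrix(0, nrow(tab), ncol(tab))
    for (b in seq_len(B)) {
      r <- off$starts[b]:off$ends[b]
      idx <- as.integer(buckets[[b]])
      for (h in seq_len(nHeads)) {
        cols <- ((h - 1) * dk + 1):(h * dk)
        A <- attn[[(b - 1) * nHeads + h]]
        gi <- g[r, cols, drop = FALSE]
        dV[r, cols] <- crossprod(A, gi)
        dA <- tcrossprod(gi, Vv[r, cols, drop = FALSE])
        dZ <- A * (dA - rowSums(dA * A))
        dS <- if (biasInsideScale) dZ * sc else dZ
        dZsc <- dZ * sc
        dQ[r, cols] <- dZsc %*% Kv[r, cols, drop = FALSE]
        dK[r, cols] <- crossprod(dZsc, Qv[r, cols, drop = FALSE])
        acc <- rowsum(as.numeric(dS), group = idx)
        ri <- as.integer(rownames(acc))
        dTab[ri, h] <- dTab[ri, h] + as.numeric(acc)
      }
    }
    list(dQ, dK, dV, dTab)
  })
}
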