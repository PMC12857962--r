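#' @title Reverse-mode automatic differentiation tape
#'
#' @description
#' A minimal define-by-run autodiff engine over dense numeric matrices.
#' Every operation pushes a node (value + backward closure) onto a tape;
#' \code{adBackward()} walks the tape in reverse, accumulating gradients.
#' All neural components of the package (graph transformer, pooling,
#' fusion, losses) are built from these primitives plus the fused
#' segmented ops in \code{nn-ops.R}.
#'
#' Values are always numeric matrices (scalars are 1x1). Gradients have
#' the shape of the value they correspond to.
#'
#' @name autodiff
#' @keywords internal
NULL

adTape <- function(nalloc = 64L) {
  e <- new.env(parent = emptyenv())
  e$vals <- vector("list", nalloc)
  e$back <- vector("list", nalloc)
  e$n <- 0L
  class(e) <- "adTape"
  e
}

adPush <- function(tape, val, parents = integer(0), fn = NULL) {
  n <- tape$n + 1L
  if (n > length(tape$vals)) {
    length(tape$vals) <- 2L * n
    length(tape$back) <- 2L * n
  }
  tape$n <- n
  tape$vals[[n]] <- val
  if (!is.null(fn)) tape$back[[n]] <- list(parents = parents, fn = fn)
  structure(list(tape = tape, id = n), class = "adNode")
}

#' Create a leaf node (input or trainable parameter)
#' @noRd
adLeaf <- function(tape, value) {
  if (!is.matrix(value)) value <- as.matrix(value)
  adPush(tape, value)
}

adVal <- function(x) {
  if (inherits(x, "adNode")) x$tape$vals[[x$id]] else x
}

#' Backpropagate from a node; gradients stored on the tape.
#' @noRd
adBackward <- function(node, seed = NULL) {
  tape <- node$tape
  grads <- vector("list", tape$n)
  v <- tape$vals[[node$id]]
  grads[[node$id]] <- if (is.null(seed)) {
    matrix(1, nrow(v), ncol(v))
  } else {
    seed
  }
  for (i in seq(node$id, 1L)) {
    g <- grads[[i]]
    if (is.null(g)) next
    b <- tape$back[[i]]
    if (is.null(b)) next
    pg <- b$fn(g)
    ps <- b$parents
    for (k in seq_along(ps)) {
      gk <- pg[[k]]
      if (is.null(gk)) next
      p <- ps[k]
      grads[[p]] <- if (is.null(grads[[p]])) gk else grads[[p]] + gk
    }
  }
  tape$grads <- grads
  invisible(grads)
}

adGrad <- function(node) {
  g <- node$tape$grads[[node$id]]
  if (is.null(g)) {
    v <- adVal(node)
    g <- matrix(0, nrow(v), ncol(v))
  }
  g
}

## ---- binary / unary primitives -------------------------------------------

adMatmul <- function(a, b) {
  A <- adVal(a); B <- adVal(b)
  adPush(a$tape, A %*% B, c(a$id, b$id), function(g) {
    list(tcrossprod(g, B), crossprod(A, g))
  })
}

adAdd <- function(a, b) {
  A <- adVal(a); B <- adVal(b)
  adPush(a$tape, A + B, c(a$id, b$id), function(g) list(g, g))
}

adSub <- function(a, b) {
  A <- adVal(a); B <- adVal(b)
  adPush(a$tape, A - B, c(a$id, b$id), function(g) list(g, -g))
}

adMul <- function(a, b) {
  A <- adVal(a); B <- adVal(b)
  adPush(a$tape, A * B, c(a$id, b$id), function(g) list(g * B, g * A))
}

#' Add a 1 x d bias row to every row of an n x d matrix
#' @noRd
adAddBiasRow <- function(x, bias) {
  X <- adVal(x); Bv <- adVal(bias)
  adPush(x$tape, sweep(X, 2L, as.numeric(Bv), "+"), c(x$id, bias$id),
         function(g) list(g, matrix(colSums(g), 1L)))
}

adScale <- function(x, s) {
  X <- adVal(x)
  adPush(x$tape, X * s, x$id, function(g) list(g * s))
}

#' Add a constant matrix (no gradient through the constant)
#' @noRd
adAddConst <- function(x, const) {
  X <- adVal(x)
  adPush(x$tape, X + const, x$id, function(g) list(g))
}

adTranspose <- function(x) {
  adPush(x$tape, t(adVal(x)), x$id, function(g) list(t(g)))
}

adRelu <- function(x) {
  X <- adVal(x)
  Y <- X * (X > 0)
  adPush(x$tape, Y, x$id, function(g) list(g * (X > 0)))
}

## tanh approximation of the Gaussian error linear unit (C++ kernel)
adGelu <- function(x) {
  X <- adVal(x)
  f <- cpp_gelu_fwd(X)
  adPush(x$tape, f$Y, x$id, function(g) {
    list(cpp_gelu_bwd(X, f$TH, g))
  })
}

adSigmoid <- function(x) {
  X <- adVal(x)
  Y <- 1 / (1 + exp(-X))
  adPush(x$tape, Y, x$id, function(g) list(g * Y * (1 - Y)))
}

adTanh <- function(x) {
  Y <- tanh(adVal(x))
  adPush(x$tape, Y, x$id, function(g) list(g * (1 - Y^2)))
}

adLog <- function(x) {
  X <- adVal(x)
  adPush(x$tape, log(X), x$id, function(g) list(g / X))
}

adExp <- function(x) {
  Y <- exp(adVal(x))
  adPush(x$tape, Y, x$id, function(g) list(g * Y))
}

adAbs <- function(x) {
  X <- adVal(x)
  adPush(x$tape, abs(X), x$id, function(g) list(g * sign(X)))
}

adSquare <- function(x) {
  X <- adVal(x)
  adPush(x$tape, X^2, x$id, function(g) list(2 * g * X))
}

adSumAll <- function(x) {
  X <- adVal(x)
  adPush(x$tape, matrix(sum(X), 1L, 1L), x$id, function(g) {
    list(matrix(as.numeric(g), nrow(X), ncol(X)))
  })
}

adMeanAll <- function(x) {
  X <- adVal(x)
  N <- length(X)
  adPush(x$tape, matrix(sum(X) / N, 1L, 1L), x$id, function(g) {
    list(matrix(as.numeric(g) / N, nrow(X), ncol(X)))
  })
}

adRowSums <- function(x) {
  X <- adVal(x)
  adPush(x$tape, matrix(rowSums(X), ncol = 1L), x$id, function(g) {
    list(matrix(rep(as.numeric(g), ncol(X)), nrow(X), ncol(X)))
  })
}

#' Row-wise softmax of an n x d matrix
#' @noRd
adSoftmaxRows <- function(x) {
  X <- adVal(x)
  E <- exp(X - rowMaxs(X))
  P <- E / rowSums(E)
  adPush(x$tape, P, x$id, function(g) {
    list(P * (g - rowSums(g * P)))
  })
}

#' log(sum(exp(x))) over each row, returned as an n x 1 column
#' @noRd
adLogSumExpRows <- function(x) {
  X <- adVal(x)
  mx <- rowMaxs(X)
  E <- exp(X - mx)
  S <- rowSums(E)
  adPush(x$tape, matrix(log(S) + mx, ncol = 1L), x$id, function(g) {
    list((E / S) * as.numeric(g))
  })
}

#' Layer normalization across each row, with gain and bias (1 x d each)
#' @noRd
adLayerNorm <- function(x, gain, bias, eps = 1e-5) {
  X <- adVal(x)
  G <- as.numeric(adVal(gain)); Bv <- as.numeric(adVal(bias))
  f <- cpp_layernorm_fwd(X, G, Bv, eps)
  adPush(x$tape, f$Y, c(x$id, gain$id, bias$id), function(g) {
    b <- cpp_layernorm_bwd(f$XN, f$istd, G, g)
    list(b$dX, matrix(b$dGain, 1L), matrix(b$dBias, 1L))
  })
}

#' Inverted dropout; identity when training = FALSE or p = 0
#' @noRd
adDropout <- function(x, p, training) {
  if (!training || p <= 0) return(x)
  X <- adVal(x)
  keep <- matrix(stats::runif(length(X)) >= p, nrow(X), ncol(X)) / (1 - p)
  adPush(x$tape, X * keep, x$id, function(g) list(g * keep))
}

#' Column-concatenate a list of nodes (same row count)
#' @noRd
adConcatCols <- function(nodes) {
  vals <- lapply(nodes, adVal)
  widths <- vapply(vals, ncol, 1L)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  out <- do.call(cbind, vals)
  adPush(nodes[[1L]]$tape, out, vapply(nodes, function(n) n$id, 1L),
         function(g) {
           lapply(seq_along(widths), function(k) {
             g[, starts[k]:ends[k], drop = FALSE]
           })
         })
}

#' Gather rows by (possibly repeated) index; backward scatter-adds
#' @noRd
adRowsGather <- function(x, idx) {
  X <- adVal(x)
  idx <- as.integer(idx)
  adPush(x$tape, X[idx, , drop = FALSE], x$id, function(g) {
    out <- matrix(0, nrow(X), ncol(X))
    acc <- rowsum(g, group = idx)
    out[as.integer(rownames(acc)), ] <- acc
    list(out)
  })
}

#' L2-normalize each row (safe at the origin via eps)
#' @noRd
adL2NormalizeRows <- function(x, eps = 1e-12) {
  X <- adVal(x)
  nrm <- sqrt(rowSums(X^2) + eps)
  Y <- X / nrm
  adPush(x$tape, Y, x$id, function(g) {
    dot <- rowSums(g * Y)
    list((g - Y * dot) / nrm)
  })
}

#' x %*% t(y) in one node
#' @noRd
adTcrossprodNode <- function(x, y) {
  X <- adVal(x); Y <- adVal(y)
  adPush(x$tape, tcrossprod(X, Y), c(x$id, y$id), function(g) {
    list(g %*% Y, crossprod(g, X))
  })
}

#' Select columns
#' @noRd
adCols <- function(x, cols) {
  X <- adVal(x)
  cols <- as.integer(cols)
  adPush(x$tape, X[, cols, drop = FALSE], x$id, function(g) {
    out <- matrix(0, nrow(X), ncol(X))
    out[, cols] <- g
    list(out)
  })
}

#' Clamp values into [lo, hi]; gradient passes only inside the interval
#' @noRd
adClamp <- function(x, lo, hi) {
  X <- adVal(x)
  Y <- pmin(pmax(X, lo), hi)
  adPush(x$tape, Y, x$id, function(g) list(g * (X > lo & X < hi)))
}

#' Elementwise multiply by a constant matrix (same shape)
#' @noRd
adMulConst <- function(x, const) {
  X <- adVal(x)
  adPush(x$tape, X * const, x$id, function(g) list(g * const))
}

#' Multiply every row of X by the matching entry of a column node
#' @noRd
adMulColBroadcast <- function(x, col) {
  X <- adVal(x)
  cv <- as.numeric(adVal(col))
  adPush(x$tape, X * cv, c(x$id, col$id), function(g) {
    list(g * cv, matrix(rowSums(g * X), ncol = 1L))
  })
}

#' Numerically stable log(1 + exp(x))
#' @noRd
adSoftplus <- function(x) {
  X <- adVal(x)
  Y <- ifelse(X > 30, X, log1p(exp(pmin(X, 30))))
  Y <- matrix(Y, nrow(X), ncol(X))
  adPush(x$tape, Y, x$id, function(g) list(g / (1 + exp(-X))))
}
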