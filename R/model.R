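## Model assembly: parameter initialization, per-drug precomputation,
## and the batched forward pass from featurized graphs + SMILES tokens
## to fused drug vectors h_final. All learnable tensors live in one
## named list; the forward builds an autodiff tape per call.

.SMILES_VOCAB <- c("<unk>", "Cl", "Br",
                   "B", "C", "N", "O", "P", "S", "F", "I",
                   "b", "c", "n", "o", "p", "s",
                   "0", "1", "2", "3", "4", "5", "6", "7", "8", "9",
                   "-", "=", "#", ":", "(", ")", "[", "]", "+", "H", "*")

#' Tokenize a SMILES string for the sequence encoder
#'
#' Greedy longest-match over the character vocabulary; two-character
#' element tokens (Cl, Br) are atomic. Unknown characters map to
#' \code{<unk>}.
#'
#' @param smiles a SMILES string.
#' @param vocab token vocabulary (default: the package's SMILES
#'   character set).
#' @return integer vector of 1-based token ids.
#' @export
tokenizeSmiles <- function(smiles, vocab = .SMILES_VOCAB) {
  chars <- strsplit(smiles, "")[[1]]
  ids <- integer(0)
  i <- 1L
  while (i <= length(chars)) {
    if (i < length(chars)) {
      two <- paste0(chars[i], chars[i + 1L])
      j <- match(two, vocab)
      if (!is.na(j)) {
        ids <- c(ids, j)
        i <- i + 2L
        next
      }
    }
    j <- match(chars[i], vocab)
    ids <- c(ids, if (is.na(j)) 1L else j)
    i <- i + 1L
  }
  ids
}

xavier <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / (nin + nout))), nin, nout)
}
zeros <- function(nr, nc) matrix(0, nr, nc)

#' Initialize a DDIModel
#'
#' Builds all parameter tensors for the configured architecture:
#' graph-transformer encoder with a shared spatial-bias bucket table,
#' DiffPool assignment/embedding maps, global attention pooling, the
#' SMILES sequence encoder, cross-attention and adaptive-fusion gate,
#' contrastive projection head, and the pair prediction MLP. Xavier
#' initialization; the spatial bias table starts at zero so attention
#' begins as standard scaled dot-product.
#'
#' @param config a \code{\link{runConfig}}.
#' @param schema feature schema (defines the input width).
#' @return a \linkS4class{DDIModel}.
#' @export
initModel <- function(config = runConfig(), schema = featureSchema()) {
  d <- config$d_model
  H <- config$n_heads
  attnOn <- !config$gcn_baseline_mode
  spatialOn <- config$spatial_bias_on && !config$standard_transformer_mode &&
    attnOn
  poolOn <- config$use_hier_pool && !config$standard_transformer_mode
  p <- list()
  p$W_in <- xavier(schema$d_atom, d); p$b_in <- zeros(1, d)
  p$mask_token <- matrix(stats::rnorm(d, sd = 0.02), 1, d)
  if (spatialOn) p$bias_table <- zeros(config$d_max + 2L, H)
  for (l in seq_len(config$n_layers)) {
    pre <- sprintf("enc%d_", l)
    p[[paste0(pre, "ln1_g")]] <- matrix(1, 1, d)
    p[[paste0(pre, "ln1_b")]] <- zeros(1, d)
    if (attnOn) {
      p[[paste0(pre, "Wq")]] <- xavier(d, d)
      p[[paste0(pre, "Wk")]] <- xavier(d, d)
    }
    p[[paste0(pre, "Wv")]] <- xavier(d, d)
    p[[paste0(pre, "Wo")]] <- xavier(d, d)
    p[[paste0(pre, "bo")]] <- zeros(1, d)
    p[[paste0(pre, "ln2_g")]] <- matrix(1, 1, d)
    p[[paste0(pre, "ln2_b")]] <- zeros(1, d)
    p[[paste0(pre, "W1")]] <- xavier(d, d * config$ffn_mult)
    p[[paste0(pre, "b1")]] <- zeros(1, d * config$ffn_mult)
    p[[paste0(pre, "W2")]] <- xavier(d * config$ffn_mult, d)
    p[[paste0(pre, "b2")]] <- zeros(1, d)
  }
  p$ln_f_g <- matrix(1, 1, d); p$ln_f_b <- zeros(1, d)
  ## hierarchical pooling
  if (poolOn) p$W_assign <- xavier(d, config$k2_cap)
  p$W_embed <- xavier(d, d)
  p$w_gate <- xavier(d, 1)
  p$W_val <- xavier(d, d)
  p$b_val <- zeros(1, d)
  if (config$fusion_on) {
    ## sequence encoder
    db <- config$d_bert
    p$tok_embed <- matrix(stats::rnorm(length(.SMILES_VOCAB) * db, sd = 0.02),
                          length(.SMILES_VOCAB), db)
    for (l in seq_len(config$seq_layers)) {
      pre <- sprintf("seq%d_", l)
      p[[paste0(pre, "ln1_g")]] <- matrix(1, 1, db)
      p[[paste0(pre, "ln1_b")]] <- zeros(1, db)
      p[[paste0(pre, "Wq")]] <- xavier(db, db)
      p[[paste0(pre, "Wk")]] <- xavier(db, db)
      p[[paste0(pre, "Wv")]] <- xavier(db, db)
      p[[paste0(pre, "Wo")]] <- xavier(db, db)
      p[[paste0(pre, "bo")]] <- zeros(1, db)
      p[[paste0(pre, "ln2_g")]] <- matrix(1, 1, db)
      p[[paste0(pre, "ln2_b")]] <- zeros(1, db)
      p[[paste0(pre, "W1")]] <- xavier(db, db * config$ffn_mult)
      p[[paste0(pre, "b1")]] <- zeros(1, db * config$ffn_mult)
      p[[paste0(pre, "W2")]] <- xavier(db * config$ffn_mult, db)
      p[[paste0(pre, "b2")]] <- zeros(1, db)
    }
    p$seq_ln_f_g <- matrix(1, 1, db); p$seq_ln_f_b <- zeros(1, db)
    ## cross-attention (graph queries over token states)
    p$W_xq <- xavier(d, db)
    p$W_xk <- xavier(db, db)
    p$W_xv <- xavier(db, d)
    ## smiles -> d_model projection + adaptive gate
    p$W_sproj <- xavier(db, d)
    p$b_sproj <- zeros(1, d)
    if (config$adaptive_fusion_on) {
      p$W_gate1 <- xavier(2 * d, 64)
      p$b_gate1 <- zeros(1, 64)
      p$W_gate2 <- xavier(64, 1)
      p$b_gate2 <- zeros(1, 1)
    }
  }
  if (config$use_contrastive) {
    ## contrastive projection head
    p$W_proj1 <- xavier(d, d)
    p$b_proj1 <- zeros(1, d)
    p$W_proj2 <- xavier(d, config$projection_dim)
    p$b_proj2 <- zeros(1, config$projection_dim)
  }
  ## pair prediction head
  h1 <- config$head_dims[1]; h2 <- config$head_dims[2]
  p$W_head1 <- xavier(4 * d, h1); p$b_head1 <- zeros(1, h1)
  p$W_head2 <- xavier(h1, h2); p$b_head2 <- zeros(1, h2)
  p$W_head3 <- xavier(h2, 1); p$b_head3 <- zeros(1, 1)

  new("DDIModel", params = p, config = unclass(config), vocab = .SMILES_VOCAB)
}

#' Count parameters of a model
#' @param model a \linkS4class{DDIModel}
#' @return integer total number of scalar parameters
#' @export
parameterCount <- function(model) {
  sum(vapply(model@params, length, 1L))
}

#' Precompute per-graph constants used by every forward pass
#'
#' Featurizes the graph, computes chemical-distance buckets and the
#' normalized adjacency used by the message-passing baseline, and
#' tokenizes the SMILES. Cached once per drug.
#' @noRd
precomputeGraph <- function(graph, config, schema = featureSchema()) {
  g <- if (nrow(graph@atomFeatures) == numAtoms(graph) &&
           numAtoms(graph) > 0) graph else featurize(graph, schema)
  n <- numAtoms(g)
  sp <- chemicalDistance(g, config$weight_scheme)
  buckets <- distanceBuckets(sp, config$d_max)
  A <- g@adjacency
  Ah <- A + diag(n)
  dg <- rowSums(Ah)
  Anorm <- Ah / sqrt(dg) / rep(sqrt(dg), each = n)
  toks <- tokenizeSmiles(g@smiles)
  if (length(toks) > config$seq_max_len) toks <- toks[seq_len(config$seq_max_len)]
  list(Xv = g@atomFeatures, n = n, buckets = buckets, adjNorm = Anorm,
       tokens = toks, mask = g@maskFlags, dist = sp$dist)
}

sinusoidalPositions <- function(L, d) {
  pos <- matrix(0, L, d)
  for (j in seq_len(d)) {
    rate <- 1 / 10000^(2 * floor((j - 1) / 2) / d)
    pos[, j] <- if (j %% 2 == 1) sin(seq_len(L) * rate) else
      cos(seq_len(L) * rate)
  }
  pos
}

## one pre-norm transformer block over stacked segments
.encoderBlock <- function(Hn0, leaves, pre, biasTab, buckets, sizes, cfg,
                          training, nHeads, dModel, gcnMats = NULL) {
  L <- function(nm) leaves[[paste0(pre, nm)]]
  Hn <- adLayerNorm(Hn0, L("ln1_g"), L("ln1_b"))
  if (!is.null(gcnMats)) {
    ## message-passing baseline: normalized-adjacency mixing replaces
    ## attention, value/output projections retained
    mixed <- adBlockConstMatmul(gcnMats, adMatmul(Hn, L("Wv")), sizes)
    att <- adLinear(mixed, L("Wo"), L("bo"))
  } else {
    Q <- adMatmul(Hn, L("Wq"))
    K <- adMatmul(Hn, L("Wk"))
    V <- adMatmul(Hn, L("Wv"))
    cat_ <- adBlockMultiHead(Q, K, V, biasTab, buckets, sizes, nHeads,
                             biasInsideScale = cfg$spatial_bias_inside_scale)
    att <- adLinear(cat_, L("Wo"), L("bo"))
  }
  H1 <- adAdd(Hn0, adDropout(att, cfg$dropout, training))
  Hn2 <- adLayerNorm(H1, L("ln2_g"), L("ln2_b"))
  ff <- adLinear(adGelu(adLinear(Hn2, L("W1"), L("b1"))), L("W2"), L("b2"))
  adAdd(H1, adDropout(ff, cfg$dropout, training))
}

#' Forward pass: encode a batch of precomputed graphs to drug vectors
#'
#' Returns tape nodes for the fused representation (\code{h_final}), the
#' molecule vector from the hierarchical readout (\code{h_mol}), atom
#' states (\code{H1}) and the pooled sequence vector. The caller owns
#' the tape and may chain losses onto the returned nodes.
#' @noRd
encodeBatch <- function(tape, leaves, items, cfg, training = FALSE) {
  sizes <- vapply(items, function(x) as.integer(x$n), 1L)
  X <- adLeaf(tape, do.call(rbind, lapply(items, function(x) x$Xv)))
  Xp <- adLinear(X, leaves$W_in, leaves$b_in)
  maskFlags <- unlist(lapply(items, function(x) x$mask))
  if (any(maskFlags)) {
    mcol <- adLeaf(tape, matrix(as.numeric(maskFlags), ncol = 1))
    keep <- matrix(1 - as.numeric(maskFlags), nrow(adVal(Xp)),
                   ncol(adVal(Xp)))
    Xp <- adAdd(adMulConst(Xp, keep), adMatmul(mcol, leaves$mask_token))
  }

  buckets <- lapply(items, `[[`, "buckets")
  spatialOn <- cfg$spatial_bias_on && !cfg$standard_transformer_mode
  biasTab <- if (spatialOn) leaves$bias_table else
    adLeaf(tape, zeros(cfg$d_max + 2L, cfg$n_heads))
  gcnMats <- if (cfg$gcn_baseline_mode) lapply(items, `[[`, "adjNorm") else NULL

  H <- Xp
  for (l in seq_len(cfg$n_layers)) {
    H <- .encoderBlock(H, leaves, sprintf("enc%d_", l), biasTab, buckets,
                       sizes, cfg, training, cfg$n_heads, cfg$d_model,
                       gcnMats = gcnMats)
  }
  H1 <- adLayerNorm(H, leaves$ln_f_g, leaves$ln_f_b)

  ## sequence branch
  hSeqPooled <- NULL
  tokenStates <- NULL
  sizesL <- NULL
  if (cfg$fusion_on) {
    toks <- lapply(items, `[[`, "tokens")
    sizesL <- vapply(toks, length, 1L)
    E <- adRowsGather(leaves$tok_embed, unlist(toks))
    posc <- do.call(rbind, lapply(sizesL, function(L) {
      sinusoidalPositions(L, cfg$d_bert)
    }))
    Ts <- adAddConst(E, posc)
    trivialBuckets <- lapply(sizesL, function(L) matrix(1L, L, L))
    zeroTab <- adLeaf(tape, zeros(1L, cfg$seq_heads))
    for (l in seq_len(cfg$seq_layers)) {
      Ts <- .encoderBlock(Ts, leaves, sprintf("seq%d_", l), zeroTab,
                          trivialBuckets, sizesL, cfg, training,
                          cfg$seq_heads, cfg$d_bert)
    }
    tokenStates <- adLayerNorm(Ts, leaves$seq_ln_f_g, leaves$seq_ln_f_b)
    hSeqPooled <- adSegmentMean(tokenStates, sizesL)

    ## cross-attention: atoms query token states, residual into H1
    Qg <- adMatmul(H1, leaves$W_xq)
    Tk <- adMatmul(tokenStates, leaves$W_xk)
    Tv <- adMatmul(tokenStates, leaves$W_xv)
    H1 <- adAdd(H1, adBlockCrossAttention(Qg, Tk, Tv, sizes, sizesL))
  }

  ## hierarchical readout
  if (cfg$use_hier_pool && !cfg$standard_transformer_mode) {
    sizesK <- vapply(sizes, k2For, 1L, cfg = cfg)
    logits <- adMatmul(H1, leaves$W_assign)
    S2 <- adRowSoftmaxVarCols(logits, sizes, sizesK)
    Z <- adMatmul(H1, leaves$W_embed)
    H2 <- adSegmentPool(S2, Z, sizes, sizesK)
  } else {
    ## identity-like assignment: every atom is its own cluster
    sizesK <- sizes
    S2 <- NULL
    H2 <- adMatmul(H1, leaves$W_embed)
  }
  gateRaw <- adMatmul(H2, leaves$w_gate)
  gate <- adSegmentSoftmax(gateRaw, sizesK)
  vals <- adLinear(H2, leaves$W_val, leaves$b_val)
  hMol <- adSegmentWeightedSum(gate, vals, sizesK)

  ## adaptive fusion
  if (cfg$fusion_on) {
    hS <- adLinear(hSeqPooled, leaves$W_sproj, leaves$b_sproj)
    if (cfg$adaptive_fusion_on) {
      gcat <- adConcatCols(list(hMol, hS))
      gh <- adRelu(adLinear(gcat, leaves$W_gate1, leaves$b_gate1))
      lam <- adSigmoid(adLinear(gh, leaves$W_gate2, leaves$b_gate2))
    } else {
      lam <- adLeaf(tape, matrix(0.5, length(sizes), 1))
    }
    oneMinus <- adAddConst(adScale(lam, -1), matrix(1, length(sizes), 1))
    hFinal <- adAdd(adMulColBroadcast(hMol, lam),
                    adMulColBroadcast(hS, oneMinus))
  } else {
    lam <- NULL
    hFinal <- hMol
  }

  list(h_final = hFinal, h_mol = hMol, H1 = H1, h_smiles = hSeqPooled,
       lambda = lam, S2 = S2, sizes = sizes, sizesK = sizesK,
       sizesL = sizesL, gate = gate)
}

#' Parameters as tape leaves
#' @noRd
paramLeaves <- function(tape, params) {
  lapply(params, function(p) adLeaf(tape, p))
}

#' Collect gradients for every parameter leaf after adBackward
#' @noRd
paramGrads <- function(leaves) {
  lapply(leaves, adGrad)
}
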