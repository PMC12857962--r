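## Three-phase training: (1) contrastive pretraining on augmented
## views, (2) joint optimization of the composite objective, (3)
## fine-tuning at a reduced learning rate with the spatial-bias table
## frozen. Adam with cosine-annealed learning rate, global gradient
## norm clipping, and validation-loss early stopping.

adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

#' One Adam step with global-norm clipping; returns updated params/state
#' @noRd
adamStep <- function(params, grads, state, lr, clip = 1.0,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                     freeze = character(0)) {
  gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), 1)))
  if (is.finite(gn) && gn > clip) {
    grads <- lapply(grads, function(g) g * (clip / gn))
  }
  state$t <- state$t + 1L
  c1 <- 1 - 0.9^state$t
  c2 <- 1 - 0.999^state$t
  for (nm in names(params)) {
    if (nm %in% freeze) next
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

cosineLr <- function(base, epoch, total) {
  if (total <= 1) return(base)
  base * 0.5 * (1 + cos(pi * (epoch - 1) / (total - 1)))
}

## encode originals + one augmented view per item; contrastive loss
## node. `encO` may carry an already-encoded original batch for reuse.
.contrastiveTerm <- function(tape, leaves, items, viewItems, cfg,
                             encO = NULL) {
  if (is.null(encO)) encO <- encodeBatch(tape, leaves, items, cfg,
                                         training = TRUE)
  encV <- encodeBatch(tape, leaves, viewItems, cfg, training = TRUE)
  Z <- projectEmbeddings(encO$h_final, leaves)
  Zp <- projectEmbeddings(encV$h_final, leaves)
  hardSets <- NULL
  if (cfg$use_hard_mining) {
    k <- min(cfg$hard_negative_k, nrow(adVal(Z)) - 1L)
    hardSets <- mineHardNegatives(adVal(Z), k)
  }
  mode <- if (cfg$denominator_mode == "with_positive") "with_positive"
          else "literal"
  contrastiveLossNode(Z, Zp, cfg$temperature, mode = mode,
                      hardSets = hardSets)
}

## Precompute augmented views for a set of drugs. Views that keep the
## original topology (atom masking; bond re-typing under unit path
## weights, which leaves shortest paths and adjacency unchanged) reuse
## the cached distance buckets instead of recomputing them.
.augItems <- function(drugs, idx, cfg, pool, cache = NULL) {
  lapply(idx, function(i) {
    v <- makeViews(drugs@graphs[[i]], cfg, pool)[[1]]
    base <- if (is.null(cache)) NULL else cache[[i]]
    if (!is.null(base)) {
      if ((v$operator == "atom_mask" && cfg$mask_mode == "token") ||
          (v$operator == "scaffold_hop" && !isTRUE(v$provenance$hopped)) ||
          (v$operator == "bond_perturb" && cfg$weight_scheme == "unit")) {
        g <- featurize(v$view)
        out <- base
        out$Xv <- g@atomFeatures
        out$mask <- g@maskFlags
        if (v$operator == "bond_perturb") {
          toks <- tokenizeSmiles(g@smiles)
          if (length(toks) > cfg$seq_max_len) {
            toks <- toks[seq_len(cfg$seq_max_len)]
          }
          out$tokens <- toks
        }
        return(out)
      }
    }
    precomputeGraph(featurize(v$view), cfg)
  })
}

#' Validation loss (BCE in eval mode) for early stopping
#' @noRd
.valLoss <- function(params, cfg, cache, drugs, pairs) {
  if (nrow(pairs) == 0) return(NA_real_)
  model <- new("DDIModel", params = params, config = unclass(cfg),
               vocab = .SMILES_VOCAB)
  p <- predictPairs(model, drugs, pairs, symmetrize = FALSE, cache = cache)
  bceLoss(p, pairs$label)
}

#' Train a DDI model with the three-phase protocol
#'
#' Phase 1 optimizes the contrastive objective alone on the training
#' drugs; phase 2 jointly optimizes binary cross-entropy + alpha *
#' contrastive + beta * L2; phase 3 repeats the joint objective at
#' phase3_lr_factor * lr with the spatial-bias table frozen. Each phase
#' anneals its learning rate cosine-wise. Validation BCE drives early
#' stopping (patience from config) in phases 2-3; the best-validation
#' parameters are retained.
#'
#' @param drugs a \linkS4class{DrugSet}.
#' @param split list(train, val, test) from \code{\link{makeSplit}}.
#' @param config a \code{\link{runConfig}}.
#' @param verbose print per-epoch losses.
#' @param cache optional precomputation cache from
#'   \code{\link{precomputeDrugs}} (built internally when absent).
#' @return list: model (\linkS4class{DDIModel}), history (per-epoch
#'   log data.frame).
#' @export
trainModel <- function(drugs, split, config = runConfig(),
                       verbose = FALSE, cache = NULL) {
  cfg <- config
  set.seed(cfg$seed)
  model <- initModel(cfg)
  params <- model@params
  state <- adamInit(params)
  if (is.null(cache)) cache <- precomputeDrugs(drugs, cfg)
  pool <- buildScaffoldPool(drugs)
  history <- list()
  logRow <- function(phase, epoch, loss, val) {
    history[[length(history) + 1L]] <<-
      data.frame(phase = phase, epoch = epoch, loss = loss,
                 val_loss = if (is.null(val)) NA_real_ else val)
  }

  trainDrugIdx <- if (!is.null(split$train_drugs)) {
    match(intersect(c(split$train_drugs,
                      unique(c(split$train$drug_a, split$train$drug_b))),
                    drugs@ids), drugs@ids)
  } else {
    match(unique(c(split$train$drug_a, split$train$drug_b)), drugs@ids)
  }

  ## ---- phase 1: contrastive pretraining --------------------------------
  if (cfg$use_contrastive && cfg$phase1_epochs > 0) {
    for (ep in seq_len(cfg$phase1_epochs)) {
      lr <- cosineLr(cfg$learning_rate, ep, cfg$phase1_epochs)
      idx <- sample(trainDrugIdx)
      bs <- min(cfg$batch_size, length(idx))
      epLoss <- 0; nb <- 0L
      viewCache <- .augItems(drugs, idx, cfg, pool, cache)
      names(viewCache) <- as.character(idx)
      for (s in seq(1, length(idx), by = bs)) {
        bidx <- idx[s:min(s + bs - 1, length(idx))]
        if (length(bidx) < 2) next
        tape <- adTape()
        leaves <- paramLeaves(tape, params)
        loss <- .contrastiveTerm(tape, leaves, cache[bidx],
                                 viewCache[as.character(bidx)], cfg)
        adBackward(loss)
        upd <- adamStep(params, paramGrads(leaves), state, lr,
                        cfg$grad_clip)
        params <- upd$params; state <- upd$state
        epLoss <- epLoss + as.numeric(adVal(loss)); nb <- nb + 1L
        if (!is.finite(epLoss)) stop("training diverged in phase 1")
      }
      logRow("contrastive", ep, epLoss / max(nb, 1L), NULL)
      if (verbose) message(sprintf("phase1 epoch %d loss %.4f", ep,
                                   epLoss / max(nb, 1L)))
    }
  }

  ## ---- phases 2 and 3: joint objective ---------------------------------
  jointPhase <- function(phaseName, epochs, lrBase, freeze) {
    bestVal <- Inf
    bestParams <- params
    wait <- 0L
    trainPairs <- split$train
    useCtr <- cfg$use_contrastive && cfg$alpha > 0
    for (ep in seq_len(epochs)) {
      lr <- cosineLr(lrBase, ep, epochs)
      ord <- sample(nrow(trainPairs))
      epLoss <- 0; nb <- 0L
      viewCache <- NULL
      if (useCtr) {
        ## fresh augmented views once per epoch, reused across batches
        viewCache <- .augItems(drugs, trainDrugIdx, cfg, pool, cache)
        names(viewCache) <- as.character(trainDrugIdx)
      }
      for (s in seq(1, nrow(trainPairs), by = cfg$batch_size)) {
        rows <- ord[s:min(s + cfg$batch_size - 1, nrow(trainPairs))]
        batch <- trainPairs[rows, , drop = FALSE]
        uids <- unique(c(batch$drug_a, batch$drug_b))
        uidx <- match(uids, drugs@ids)
        tape <- adTape()
        leaves <- paramLeaves(tape, params)
        enc <- encodeBatch(tape, leaves, cache[uidx], cfg, training = TRUE)
        pf <- pairEncodeNode(enc$h_final, match(batch$drug_a, uids),
                             match(batch$drug_b, uids))
        logits <- predictionLogits(pf, leaves, cfg, training = TRUE)
        loss <- bceLossNode(logits, batch$label, cfg$bce_reduction)
        if (useCtr && length(uidx) >= 2) {
          views <- viewCache[as.character(uidx)]
          bad <- vapply(views, is.null, TRUE)
          if (any(bad)) views[bad] <- .augItems(drugs, uidx[bad], cfg, pool, cache)
          ctr <- .contrastiveTerm(tape, leaves, cache[uidx], views, cfg,
                                  encO = enc)
          loss <- adAdd(loss, adScale(ctr, cfg$alpha))
        }
        adBackward(loss)
        grads <- paramGrads(leaves)
        if (cfg$beta > 0) {  # explicit L2 term: d(beta*||theta||^2) = 2*beta*theta
          for (nm in names(grads)) {
            grads[[nm]] <- grads[[nm]] + 2 * cfg$beta * params[[nm]]
          }
        }
        upd <- adamStep(params, grads, state, lr, cfg$grad_clip,
                        freeze = freeze)
        params <- upd$params; state <- upd$state
        epLoss <- epLoss + as.numeric(adVal(loss)); nb <- nb + 1L
        if (!is.finite(epLoss)) stop("training diverged in ", phaseName)
      }
      vl <- .valLoss(params, cfg, cache, drugs, split$val)
      logRow(phaseName, ep, epLoss / max(nb, 1L), vl)
      if (verbose) message(sprintf("%s epoch %d loss %.4f val %.4f",
                                   phaseName, ep, epLoss / max(nb, 1L),
                                   if (is.na(vl)) NaN else vl))
      if (!is.na(vl)) {
        if (vl < bestVal - 1e-6) {
          bestVal <- vl; bestParams <- params; wait <- 0L
        } else {
          wait <- wait + 1L
          if (wait >= cfg$patience) break
        }
      }
    }
    if (is.finite(bestVal)) params <<- bestParams
  }

  if (cfg$phase2_epochs > 0 && nrow(split$train) > 0) {
    jointPhase("joint", cfg$phase2_epochs, cfg$learning_rate,
               freeze = character(0))
  }
  if (cfg$phase3_epochs > 0 && nrow(split$train) > 0) {
    jointPhase("finetune", cfg$phase3_epochs,
               cfg$learning_rate * cfg$phase3_lr_factor,
               freeze = "bias_table")
  }

  list(model = new("DDIModel", params = params, config = unclass(cfg),
                   vocab = .SMILES_VOCAB),
       history = do.call(rbind, history))
}

#' Evaluate a model on labeled pairs
#'
#' @param model a \linkS4class{DDIModel}.
#' @param drugs a \linkS4class{DrugSet}.
#' @param pairs labeled pair data.frame.
#' @param threshold classification threshold.
#' @param cache optional precomputation cache.
#' @return metrics list from \code{\link{evaluatePredictions}}.
#' @export
evaluateModel <- function(model, drugs, pairs,
                          threshold = model@config$threshold,
                          cache = NULL) {
  p <- predictPairs(model, drugs, pairs, cache = cache)
  evaluatePredictions(p, pairs$label, threshold)
}

#' The component-removal variant table
#' @noRd
.ablationVariants <- function() {
  list(
    full = list(),
    no_contrastive = list(use_contrastive = FALSE, alpha = 0),
    no_hier_pool = list(use_hier_pool = FALSE),
    no_fusion = list(fusion_on = FALSE),
    no_spatial = list(spatial_bias_on = FALSE),
    no_hard_mining = list(use_hard_mining = FALSE),
    no_adaptive_fusion = list(adaptive_fusion_on = FALSE),
    standard_transformer = list(standard_transformer_mode = TRUE),
    gcn_baseline = list(gcn_baseline_mode = TRUE)
  )
}

#' Train and evaluate every ablation variant
#'
#' Runs the full model plus the eight component-removal variants on the
#' same split and seed, reporting test metrics and parameter counts.
#'
#' @param drugs a \linkS4class{DrugSet}.
#' @param split list(train, val, test).
#' @param baseConfig configuration shared by all variants.
#' @param variants "all" or a character vector of variant names.
#' @param verbose print progress.
#' @return data.frame: variant, n_params, ACC, AUC, F1, precision,
#'   recall, AP.
#' @export
runAblation <- function(drugs, split, baseConfig = runConfig(),
                        variants = "all", verbose = FALSE) {
  av <- .ablationVariants()
  if (!identical(variants, "all")) av <- av[variants]
  rows <- list()
  for (nm in names(av)) {
    cfg <- baseConfig
    for (k in names(av[[nm]])) cfg[[k]] <- av[[nm]][[k]]
    if (verbose) message("ablation variant: ", nm)
    fit <- trainModel(drugs, split, cfg)
    met <- evaluateModel(fit$model, drugs, split$test)
    rows[[nm]] <- data.frame(
      variant = nm, n_params = parameterCount(fit$model),
      ACC = met$ACC, AUC = met$AUC, F1 = met$F1,
      precision = met$precision, recall = met$recall, AP = met$AP)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
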