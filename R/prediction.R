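## Pair feature construction, the prediction MLP and the composite
## training objective: L_total = L_DDI + alpha * L_contrastive +
## beta * L_reg, with binary cross-entropy for L_DDI and an explicit
## L2 term for L_reg (optimizer weight decay stays 0).

#' Encode a drug pair
#'
#' h_pair = [h_i ; h_j ; h_i * h_j ; |h_i - h_j|] (elementwise product
#' and absolute difference). The last two blocks are symmetric under
#' swapping the pair; the first two are not, which is why inference
#' symmetrizes by default.
#'
#' @param h_i,h_j equal-length numeric vectors.
#' @return numeric vector of length 4 * length(h_i).
#' @export
pairEncode <- function(h_i, h_j) {
  if (length(h_i) != length(h_j)) stop("pair vectors differ in length")
  c(h_i, h_j, h_i * h_j, abs(h_i - h_j))
}

#' Pair features for batches, as a tape node
#' @noRd
pairEncodeNode <- function(Hfinal, ia, ib) {
  hi <- adRowsGather(Hfinal, ia)
  hj <- adRowsGather(Hfinal, ib)
  adConcatCols(list(hi, hj, adMul(hi, hj), adAbs(adSub(hi, hj))))
}

#' Prediction head: logits from pair features (tape form)
#' @noRd
predictionLogits <- function(pairFeat, leaves, cfg, training = FALSE) {
  h <- adRelu(adLinear(pairFeat, leaves$W_head1, leaves$b_head1))
  h <- adDropout(h, cfg$dropout, training)
  h <- adRelu(adLinear(h, leaves$W_head2, leaves$b_head2))
  h <- adDropout(h, cfg$dropout, training)
  adLinear(h, leaves$W_head3, leaves$b_head3)
}

#' Binary cross-entropy from logits, as a tape node
#'
#' L = sum_i [softplus(z_i) - y_i z_i], algebraically equal to
#' -sum_i [y log p + (1-y) log(1-p)] with p = sigmoid(z), computed in
#' the numerically stable logit form. \code{reduction} "mean" divides by
#' the batch size; "sum" is the literal summed objective.
#' @noRd
bceLossNode <- function(logits, y, reduction = "mean") {
  yc <- matrix(as.numeric(y), ncol = 1)
  perPair <- adSub(adSoftplus(logits), adMulConst(logits, yc))
  if (reduction == "mean") adMeanAll(perPair) else adSumAll(perPair)
}

#' Binary cross-entropy on plain probabilities
#'
#' Probabilities are clamped into [1e-7, 1 - 1e-7] before the logs.
#'
#' @param p predicted probabilities in (0,1).
#' @param y 0/1 labels.
#' @param reduction "mean" or "sum".
#' @return scalar loss.
#' @export
bceLoss <- function(p, y, reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  v <- -(y * log(p) + (1 - y) * log(1 - p))
  if (reduction == "mean") mean(v) else sum(v)
}

#' Sum of squared parameters (explicit L2 regularizer)
#' @param params named list of parameter matrices
#' @return scalar
#' @export
l2Penalty <- function(params) {
  sum(vapply(params, function(p) sum(p^2), 1))
}

#' Composite training loss on plain values
#'
#' @param p predicted probabilities.
#' @param y 0/1 labels.
#' @param contrastive scalar contrastive loss term (0 when disabled).
#' @param params parameter list for the L2 term.
#' @param alpha contrastive weight (default 0.5).
#' @param beta L2 weight (default 1e-5).
#' @param reduction BCE reduction.
#' @return scalar total loss.
#' @export
totalLoss <- function(p, y, contrastive = 0, params = list(),
                      alpha = 0.5, beta = 1e-5, reduction = "mean") {
  bceLoss(p, y, reduction) + alpha * contrastive + beta * l2Penalty(params)
}

#' Predict interaction probabilities for drug pairs
#'
#' Encodes each referenced drug once, builds pair features and applies
#' the prediction head in eval mode (dropout off, deterministic). By
#' default the prediction is symmetrized: p = (p(a,b) + p(b,a)) / 2,
#' making the result exactly invariant to pair order.
#'
#' @param model a trained \linkS4class{DDIModel}.
#' @param drugs a \linkS4class{DrugSet}.
#' @param pairs data.frame with \code{drug_a}, \code{drug_b}.
#' @param symmetrize average over both pair orders (default from the
#'   model config).
#' @param cache optional precomputation cache from
#'   \code{\link{precomputeDrugs}}.
#' @return numeric vector of probabilities, one per pair row.
#' @export
predictPairs <- function(model, drugs, pairs,
                         symmetrize = model@config$symmetrize_inference,
                         cache = NULL) {
  cfg <- model@config
  if (is.null(cache)) cache <- precomputeDrugs(drugs, cfg)
  ## deterministic encode order: identical pair sets yield bit-identical
  ## encodings regardless of row order
  used <- sort(unique(c(pairs$drug_a, pairs$drug_b)))
  missing <- setdiff(used, drugs@ids)
  if (length(missing) > 0) {
    stop("unknown drug id(s): ", paste(missing, collapse = ", "))
  }
  idx <- match(used, drugs@ids)
  tape <- adTape()
  leaves <- paramLeaves(tape, model@params)
  enc <- encodeBatch(tape, leaves, cache[idx], cfg, training = FALSE)
  ia <- match(pairs$drug_a, used)
  ib <- match(pairs$drug_b, used)
  pAB <- adVal(adSigmoid(predictionLogits(
    pairEncodeNode(enc$h_final, ia, ib), leaves, cfg)))
  if (!symmetrize) return(as.numeric(pAB))
  pBA <- adVal(adSigmoid(predictionLogits(
    pairEncodeNode(enc$h_final, ib, ia), leaves, cfg)))
  as.numeric((pAB + pBA) / 2)
}

#' Precompute encoder inputs for every drug in a set
#'
#' @param drugs a \linkS4class{DrugSet}.
#' @param config a \code{\link{runConfig}}.
#' @return list of per-drug precomputation records, named by drug id.
#' @export
precomputeDrugs <- function(drugs, config) {
  out <- lapply(drugs@graphs, precomputeGraph, config = config)
  names(out) <- drugs@ids
  out
}
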