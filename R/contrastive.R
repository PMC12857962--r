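## Contrastive objective: NT-Xent over original/augmented drug pairs
## with temperature scaling, plus cosine-similarity hard negative
## mining. Negatives are the other ORIGINAL drugs in the batch.

#' Project embeddings through the contrastive head (tape form)
#' @noRd
projectEmbeddings <- function(X, leaves) {
  h <- adRelu(adLinear(X, leaves$W_proj1, leaves$b_proj1))
  adLinear(h, leaves$W_proj2, leaves$b_proj2)
}

#' Mine hard negatives by cosine similarity
#'
#' For each anchor i, the k negatives j != i with the highest cosine
#' similarity sim(z_i, z_j). Deterministic: ties break by ascending
#' index. k greater than B-1 is clamped with a warning.
#'
#' @param Z B x d numeric matrix of anchor embeddings.
#' @param k number of hard negatives per anchor.
#' @return list of integer index vectors, one per anchor.
#' @export
mineHardNegatives <- function(Z, k) {
  B <- nrow(Z)
  if (B < 2) stop("need at least 2 embeddings to mine negatives")
  if (k > B - 1) {
    warning("hard_negative_k clamped to batch size - 1")
    k <- B - 1
  }
  Zn <- Z / sqrt(rowSums(Z^2) + 1e-12)
  S <- tcrossprod(Zn)
  lapply(seq_len(B), function(i) {
    s <- S[i, ]
    s[i] <- -Inf
    ## order(-s, idx): ties resolved by ascending index
    ord <- order(-s, seq_len(B))
    sort(ord[seq_len(k)])
  })
}

#' Contrastive loss as a tape node
#'
#' Mean over anchors of -log( exp(sim(z_i, z_i+)/tau) / D_i ), with
#' rows L2-normalized so similarity is cosine. The denominator D_i
#' depends on \code{mode}: \code{with_positive} includes the positive
#' term plus all in-batch negatives; \code{literal} uses the negatives
#' only. When \code{hardSets} is given (list of per-anchor negative
#' index sets), the denominator is the positive term plus those
#' negatives only — the hard-mining objective.
#' @noRd
contrastiveLossNode <- function(Z, Zplus, tau,
                                mode = c("with_positive", "literal"),
                                hardSets = NULL) {
  mode <- match.arg(mode)
  B <- nrow(adVal(Z))
  if (B < 2) stop("contrastive loss needs a batch of at least 2")
  Zn <- adL2NormalizeRows(Z)
  Zpn <- adL2NormalizeRows(Zplus)
  pos <- adScale(adRowSums(adMul(Zn, Zpn)), 1 / tau)        # B x 1
  simNeg <- adScale(adTcrossprodNode(Zn, Zn), 1 / tau)      # B x B
  mask <- matrix(0, B, B)
  diag(mask) <- -Inf
  if (!is.null(hardSets)) {
    mask[] <- -Inf
    for (i in seq_len(B)) mask[i, hardSets[[i]]] <- 0
  }
  masked <- adAddConst(simNeg, mask)
  den <- if (mode == "with_positive" || !is.null(hardSets)) {
    adLogSumExpRows(adConcatCols(list(masked, pos)))
  } else {
    adLogSumExpRows(masked)
  }
  adMeanAll(adSub(den, pos))
}

#' Contrastive loss on plain matrices
#'
#' Numeric front-end to the tape objective, for evaluation and testing.
#' \code{denominator_mode = "with_positive"} adds the positive pair term
#' to the in-batch negatives (bounded below by 0);
#' \code{"literal_eq12"} uses only the negatives.
#'
#' @param Z B x d anchor embeddings (originals).
#' @param Zplus B x d embeddings of the augmented views.
#' @param temperature softmax temperature (default 0.1).
#' @param denominator_mode \code{"with_positive"} or \code{"literal_eq12"}.
#' @return scalar loss.
#' @export
contrastiveLoss <- function(Z, Zplus, temperature = 0.1,
                            denominator_mode = c("with_positive",
                                                 "literal_eq12")) {
  denominator_mode <- match.arg(denominator_mode)
  t <- adTape()
  node <- contrastiveLossNode(
    adLeaf(t, Z), adLeaf(t, Zplus), temperature,
    mode = if (denominator_mode == "with_positive") "with_positive"
           else "literal")
  as.numeric(adVal(node))
}

#' Hard-negative contrastive loss on plain matrices
#'
#' Denominator = positive term + the k hardest in-batch negatives per
#' anchor. With k = B - 1 this equals \code{contrastiveLoss} in
#' \code{with_positive} mode exactly.
#'
#' @inheritParams contrastiveLoss
#' @param k hard negatives per anchor.
#' @return scalar loss.
#' @export
hardContrastiveLoss <- function(Z, Zplus, k, temperature = 0.1) {
  hs <- mineHardNegatives(Z, k)
  t <- adTape()
  node <- contrastiveLossNode(adLeaf(t, Z), adLeaf(t, Zplus), temperature,
                              mode = "with_positive", hardSets = hs)
  as.numeric(adVal(node))
}
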