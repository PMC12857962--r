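## Data splitting: transductive (pair-level), inductive (drug-level:
## test pairs touch at least one held-out drug) and scaffold-based
## inductive (no Murcko scaffold spans train and test).

#' Split labeled pairs into train/validation/test
#'
#' \code{transductive}: random pair-level partition by the configured
#' fractions (0.6/0.2/0.2). \code{inductive_random}: drugs are
#' partitioned (80% train / 20% held out, with a slice of the training
#' drugs reserved for validation); train pairs have both drugs in the
#' train set, test pairs touch at least one held-out drug, validation
#' pairs connect validation-reserved drugs. \code{inductive_scaffold}:
#' same, but whole Murcko-scaffold groups are assigned together so no
#' scaffold appears on both sides.
#'
#' @param pairs data.frame drug_a/drug_b/label.
#' @param drugs a \linkS4class{DrugSet}.
#' @param mode split mode.
#' @param fractions train/val/test fractions for transductive mode.
#' @param drug_fraction training drug fraction for inductive modes.
#' @param seed RNG seed.
#' @return list(train, val, test) of pair data.frames.
#' @export
makeSplit <- function(pairs, drugs,
                      mode = c("transductive", "inductive_random",
                               "inductive_scaffold"),
                      fractions = c(0.6, 0.2, 0.2),
                      drug_fraction = 0.8, seed = 42L) {
  mode <- match.arg(mode)
  set.seed(seed)
  nP <- nrow(pairs)
  if (mode == "transductive") {
    idx <- sample(nP)
    nTr <- round(fractions[1] * nP)
    nVa <- round(fractions[2] * nP)
    return(list(train = pairs[idx[seq_len(nTr)], , drop = FALSE],
                val = pairs[idx[nTr + seq_len(nVa)], , drop = FALSE],
                test = pairs[idx[(nTr + nVa + 1):nP], , drop = FALSE]))
  }

  ids <- drugs@ids
  nTrain <- round(drug_fraction * length(ids))
  if (nTrain < 2 || nTrain >= length(ids)) {
    stop(sprintf("cannot split %d drugs at fraction %.2f", length(ids),
                 drug_fraction))
  }
  if (mode == "inductive_random") {
    trainDrugs <- sample(ids)[seq_len(nTrain)]
  } else {
    ## group drugs by scaffold and assign whole groups to the training
    ## side until its quota is reached, so no scaffold spans the split
    key <- vapply(drugs@graphs, function(g) {
      sc <- murckoScaffold(g)
      if (length(sc) == 0) paste0("acyclic:", stats::runif(1)) else
        writeSmiles(inducedSubgraph(g, sc))
    }, "")
    groups <- split(ids, key)
    groups <- groups[sample(length(groups))]
    sizes <- cumsum(lengths(groups))
    take <- which(sizes <= nTrain)
    if (length(take) == 0) take <- 1L
    trainDrugs <- unlist(groups[take], use.names = FALSE)
    if (length(trainDrugs) >= length(ids)) {
      stop("scaffold groups too coarse to honor the drug fraction")
    }
  }
  heldOut <- setdiff(ids, trainDrugs)
  ## reserve a fifth of the training drugs for validation pairs
  nVal <- max(1L, round(0.2 * nTrain))
  valDrugs <- trainDrugs[seq_len(nVal)]
  coreTrain <- setdiff(trainDrugs, valDrugs)

  inA <- pairs$drug_a %in% coreTrain
  inB <- pairs$drug_b %in% coreTrain
  vaA <- pairs$drug_a %in% valDrugs
  vaB <- pairs$drug_b %in% valDrugs
  heldA <- pairs$drug_a %in% heldOut
  heldB <- pairs$drug_b %in% heldOut
  test <- pairs[heldA | heldB, , drop = FALSE]
  val <- pairs[(vaA & vaB) | (vaA & inB) | (inA & vaB), , drop = FALSE]
  train <- pairs[inA & inB, , drop = FALSE]
  list(train = train, val = val, test = test,
       train_drugs = coreTrain, val_drugs = valDrugs, test_drugs = heldOut)
}

#' Sample negative pairs to balance a positives-only table
#'
#' Uniform random non-positive pairs at the requested ratio, excluding
#' known positives and self-pairs, seeded.
#'
#' @param positives data.frame drug_a/drug_b (label ignored).
#' @param drugs a \linkS4class{DrugSet}.
#' @param ratio negatives per positive (default 1).
#' @param seed RNG seed.
#' @return combined labeled pair data.frame, positives first.
#' @export
sampleNegatives <- function(positives, drugs, ratio = 1, seed = 42L) {
  set.seed(seed)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  seen <- unique(key(positives$drug_a, positives$drug_b))
  want <- round(ratio * nrow(positives))
  ids <- drugs@ids
  neg <- character(0)
  guard <- 0L
  while (length(neg) < want) {
    guard <- guard + 1L
    if (guard > 200L) stop("cannot sample enough negative pairs")
    a <- sample(ids, want, replace = TRUE)
    b <- sample(ids, want, replace = TRUE)
    ok <- a != b & !(key(a, b) %in% seen)
    cand <- unique(key(a, b)[ok])
    neg <- unique(c(neg, cand))
  }
  neg <- neg[seq_len(want)]
  parts <- strsplit(neg, " ")
  rbind(
    data.frame(drug_a = positives$drug_a, drug_b = positives$drug_b,
               label = 1L),
    data.frame(drug_a = vapply(parts, `[`, "", 1),
               drug_b = vapply(parts, `[`, "", 2), label = 0L))
}
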