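## Download-free synthetic benchmark: a fragment-grammar generator of
## valence-valid small molecules and a deterministic functional-group
## interaction rule that labels drug pairs, with configurable label
## noise at a 1:1 positive/negative ratio. The rule fires on detectable
## substructures, so a model can only learn it by attending to
## functional groups.

#' Generator configuration
#'
#' @param n_drugs number of molecules.
#' @param atom_range inclusive heavy-atom count range.
#' @param ring_weight relative weight of ring backbones (benzene,
#'   pyridine) vs alkyl chains; 0 disables rings entirely.
#' @param substituent_range how many functional-group substituents to
#'   attach per molecule.
#' @param rule interaction rule id (only \code{"R1"} is defined).
#' @param label_noise probability of flipping each pair label
#'   (epsilon < 0.5).
#' @param n_pairs labeled pairs to emit.
#' @param pos_ratio positive fraction (default 0.5 = the 1:1 ratio).
#' @param seed RNG seed.
#' @return a list of class \code{generatorConfig}.
#' @export
generatorConfig <- function(n_drugs = 300L, atom_range = c(6L, 24L),
                            ring_weight = 0.6,
                            substituent_range = c(0L, 3L),
                            rule = "R1", label_noise = 0,
                            n_pairs = 3000L, pos_ratio = 0.5,
                            seed = 42L) {
  stopifnot(label_noise >= 0, label_noise < 0.5,
            atom_range[1] >= 2, atom_range[2] >= atom_range[1])
  structure(list(n_drugs = n_drugs, atom_range = atom_range,
                 ring_weight = ring_weight,
                 substituent_range = substituent_range, rule = rule,
                 label_noise = label_noise, n_pairs = n_pairs,
                 pos_ratio = pos_ratio, seed = seed),
            class = c("generatorConfig", "list"))
}

## fragment vocabulary: SMILES pieces with one open attachment written
## as a leading atom that bonds to the backbone
.SUBSTITUENTS <- c(carboxyl = "C(=O)O", amine = "N", hydroxyl = "O",
                   carbonyl = "C(C)=O", sulfonyl = "S(=O)(=O)C",
                   halogen_f = "F", halogen_cl = "Cl", halogen_br = "Br",
                   methyl = "C")

#' Generate one valence-valid molecule as SMILES
#'
#' Assembles a backbone (alkyl chain, benzene or pyridine ring,
#' optionally extended by a second chain) and attaches functional-group
#' substituents from a fixed fragment vocabulary at valence-safe
#' positions, then validates by parsing. Rejection-samples until the
#' atom count lands in range (bounded retries).
#'
#' @param config a \code{\link{generatorConfig}}.
#' @return a SMILES string.
#' @export
generateMolecule <- function(config = generatorConfig()) {
  for (try in 1:50) {
    useRing <- stats::runif(1) < config$ring_weight
    if (useRing) {
      ring <- if (stats::runif(1) < 0.3) "c1ccncc1" else "c1ccccc1"
      ## open ring form with substitution slots
      backbone <- ring
      nSlots <- 3L
    } else {
      len <- sample(3:8, 1)
      backbone <- paste(rep("C", len), collapse = "")
      nSlots <- len
    }
    nSub <- sample(config$substituent_range[1]:config$substituent_range[2], 1)
    extra <- if (stats::runif(1) < 0.5) {
      paste(rep("C", sample(1:4, 1)), collapse = "")
    } else ""
    subs <- if (nSub > 0) {
      sample(.SUBSTITUENTS, nSub, replace = TRUE)
    } else character(0)
    smiles <- .assembleSmiles(backbone, useRing, subs, extra)
    g <- tryCatch(parseSmiles(smiles), error = function(e) NULL)
    if (is.null(g)) next
    n <- numAtoms(g)
    if (n >= config$atom_range[1] && n <= config$atom_range[2]) {
      return(writeSmiles(g))
    }
  }
  stop("molecule generation failed after 50 attempts")
}

.assembleSmiles <- function(backbone, isRing, subs, extra) {
  if (isRing) {
    ## insert substituents as branches on ring atoms: rewrite
    ## c1ccccc1 -> c1cc(R)ccc1-style by splitting at letters
    core <- strsplit(backbone, "")[[1]]
    atomPos <- which(core %in% c("c", "n"))
    ## never substitute the aromatic n
    atomPos <- atomPos[core[atomPos] == "c"]
    chunks <- core
    if (length(subs) > 0) {
      slots <- sample(atomPos, min(length(subs), length(atomPos)))
      for (i in seq_along(slots)) {
        chunks[slots[i]] <- paste0(chunks[slots[i]], "(", subs[i], ")")
      }
    }
    s <- paste(chunks, collapse = "")
    if (nchar(extra) > 0) s <- paste0(s, extra)
    s
  } else {
    chars <- strsplit(backbone, "")[[1]]
    if (length(subs) > 0) {
      slots <- sample(seq_along(chars), min(length(subs), length(chars)))
      for (i in seq_along(slots)) {
        chars[slots[i]] <- paste0(chars[slots[i]], "(", subs[i], ")")
      }
    }
    paste0(paste(chars, collapse = ""), extra)
  }
}

#' Deterministic functional-group interaction rule
#'
#' Rule \code{R1}: a pair interacts (label 1) iff one molecule contains
#' an amine and the other a carboxyl group, or both are aromatic and at
#' least one carries a halogen. Symmetric by construction.
#'
#' @param graph_a,graph_b parsed \linkS4class{MolecularGraph}s.
#' @param rule rule id.
#' @return 0 or 1.
#' @export
interactionRule <- function(graph_a, graph_b, rule = "R1") {
  if (!identical(rule, "R1")) {
    stop("unknown rule id '", rule, "'; available rules: R1")
  }
  fa <- functionalGroups(graph_a)$type
  fb <- functionalGroups(graph_b)$type
  has <- function(f, what) what %in% f
  amineCarboxyl <- (has(fa, "amine") && has(fb, "carboxyl")) ||
    (has(fb, "amine") && has(fa, "carboxyl"))
  aromHal <- has(fa, "aromatic_ring") && has(fb, "aromatic_ring") &&
    (has(fa, "halogen") || has(fb, "halogen"))
  as.integer(amineCarboxyl || aromHal)
}

#' Generate a labeled synthetic DDI dataset
#'
#' Draws molecules from the fragment grammar, labels candidate pairs
#' with the interaction rule, samples to the configured positive ratio
#' (within one pair of exact balance), then flips an epsilon fraction of
#' labels. Returns the drug set, the pair table, and a per-pair rule
#' trace (which clause fired, and whether the label was flipped).
#'
#' @param config a \code{\link{generatorConfig}}.
#' @return list: drugs (\linkS4class{DrugSet}), pairs (data.frame),
#'   trace (data.frame), oracle_labels (rule output before noise).
#' @export
generateDataset <- function(config = generatorConfig()) {
  set.seed(config$seed)
  smiles <- character(config$n_drugs)
  for (i in seq_len(config$n_drugs)) smiles[i] <- generateMolecule(config)
  ids <- sprintf("SD%04d", seq_len(config$n_drugs))
  drugs <- makeDrugSet(ids, smiles)

  ## label all candidate pairs lazily: sample candidates, classify, and
  ## fill the positive/negative quotas
  nPos <- round(config$n_pairs * config$pos_ratio)
  nNeg <- config$n_pairs - nPos
  fgCache <- lapply(drugs@graphs, function(g) functionalGroups(g)$type)
  ruleFor <- function(i, j) {
    fa <- fgCache[[i]]; fb <- fgCache[[j]]
    has <- function(f, w) w %in% f
    ac <- (has(fa, "amine") && has(fb, "carboxyl")) ||
      (has(fb, "amine") && has(fa, "carboxyl"))
    ah <- has(fa, "aromatic_ring") && has(fb, "aromatic_ring") &&
      (has(fa, "halogen") || has(fb, "halogen"))
    c(as.integer(ac || ah),
      if (ac) 1L else if (ah) 2L else 0L)
  }
  pos <- list(); neg <- list()
  seen <- new.env(hash = TRUE)
  guard <- 0L
  while ((length(pos) < nPos || length(neg) < nNeg) && guard < 60L) {
    guard <- guard + 1L
    a <- sample(config$n_drugs, 4L * config$n_pairs, replace = TRUE)
    b <- sample(config$n_drugs, 4L * config$n_pairs, replace = TRUE)
    ok <- a != b
    a <- a[ok]; b <- b[ok]
    lo <- pmin(a, b); hi <- pmax(a, b)
    for (t in seq_along(lo)) {
      kk <- paste0(lo[t], "_", hi[t])
      if (!is.null(seen[[kk]])) next
      seen[[kk]] <- TRUE
      r <- ruleFor(lo[t], hi[t])
      if (r[1] == 1 && length(pos) < nPos) {
        pos[[length(pos) + 1L]] <- c(lo[t], hi[t], r[2])
      } else if (r[1] == 0 && length(neg) < nNeg) {
        neg[[length(neg) + 1L]] <- c(lo[t], hi[t], r[2])
      }
      if (length(pos) >= nPos && length(neg) >= nNeg) break
    }
  }
  if (length(pos) < nPos || length(neg) < nNeg) {
    stop(sprintf(
      "pair ratio unattainable: found %d positives / %d negatives of %d/%d",
      length(pos), length(neg), nPos, nNeg))
  }
  all <- c(pos, neg)
  mat <- do.call(rbind, all)
  ruleLabel <- c(rep(1L, nPos), rep(0L, nNeg))
  flip <- stats::runif(length(ruleLabel)) < config$label_noise
  label <- as.integer(xor(ruleLabel, flip))
  perm <- sample(length(label))
  pairs <- data.frame(drug_a = ids[mat[perm, 1]], drug_b = ids[mat[perm, 2]],
                      label = label[perm])
  trace <- data.frame(drug_a = ids[mat[perm, 1]],
                      drug_b = ids[mat[perm, 2]],
                      rule_label = ruleLabel[perm],
                      clause = c("none", "amine_carboxyl",
                                 "aromatic_halogen")[mat[perm, 3] + 1L],
                      flipped = flip[perm])
  list(drugs = drugs, pairs = pairs, trace = trace,
       oracle_labels = ruleLabel[perm], config = config)
}

#' Write a synthetic dataset to disk
#'
#' Emits the drug table, pair table, rule trace TSV and a manifest JSON
#' with the generator configuration.
#'
#' @param dataset result of \code{\link{generateDataset}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the written paths.
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    drugs = file.path(dir, "drugs.tsv"),
    pairs = file.path(dir, "pairs.tsv"),
    trace = file.path(dir, "rule_trace.tsv"),
    manifest = file.path(dir, "manifest.json"))
  writeDrugTable(dataset$drugs, paths["drugs"])
  writePairTable(dataset$pairs, paths["pairs"])
  utils::write.table(dataset$trace, paths["trace"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(dataset$config), paths["manifest"],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
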