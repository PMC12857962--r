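## On-disk formats: UTF-8 TSV with a header row.
##   drug table:  drug_id <TAB> smiles
##   pair table:  drug_a <TAB> drug_b [<TAB> label]
##   predictions: drug_a <TAB> drug_b <TAB> probability (6 decimals)

#' Read a drug table into a DrugSet
#'
#' Parses every SMILES; a parse or valence failure propagates with the
#' offending drug id prefixed.
#'
#' @param path TSV file with header \code{drug_id}, \code{smiles}.
#' @return a \linkS4class{DrugSet}.
#' @export
readDrugTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("drug_id", "smiles") %in% names(df))) {
    stop("drug table must have columns drug_id, smiles: ", path)
  }
  makeDrugSet(df$drug_id, df$smiles)
}

#' Build a DrugSet from vectors of ids and SMILES
#' @param ids unique drug identifiers
#' @param smiles SMILES strings, parallel to \code{ids}
#' @export
makeDrugSet <- function(ids, smiles) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) {
    stop("duplicate drug ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  graphs <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    graphs[[i]] <- tryCatch(parseSmiles(smiles[i]), error = function(e) {
      stop(sprintf("drug %s: %s", ids[i], conditionMessage(e)), call. = FALSE)
    })
  }
  new("DrugSet", ids = ids, smiles = as.character(smiles), graphs = graphs)
}

#' Write a DrugSet as a TSV drug table
#' @param drugs a \linkS4class{DrugSet}
#' @param path output file
#' @export
writeDrugTable <- function(drugs, path) {
  utils::write.table(
    data.frame(drug_id = drugs@ids, smiles = drugs@smiles),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a labeled (or unlabeled) pair table
#'
#' @param path TSV with header \code{drug_a}, \code{drug_b} and
#'   optionally \code{label}.
#' @param drugs optional \linkS4class{DrugSet}; when given, every
#'   referenced id must resolve, otherwise an error lists all missing
#'   ids.
#' @return data.frame with columns \code{drug_a}, \code{drug_b} and
#'   \code{label} (NA when absent).
#' @export
readPairTable <- function(path, drugs = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("drug_a", "drug_b") %in% names(df))) {
    stop("pair table must have columns drug_a, drug_b: ", path)
  }
  if (!"label" %in% names(df)) df$label <- NA_integer_
  df$drug_a <- as.character(df$drug_a)
  df$drug_b <- as.character(df$drug_b)
  if (!all(is.na(df$label)) &&
      !all(df$label[!is.na(df$label)] %in% c(0L, 1L))) {
    stop("pair labels must be 0/1")
  }
  if (!is.null(drugs)) {
    missing <- setdiff(unique(c(df$drug_a, df$drug_b)), drugs@ids)
    if (length(missing) > 0) {
      stop("pair table references unknown drug id(s): ",
           paste(missing, collapse = ", "))
    }
  }
  df[, c("drug_a", "drug_b", "label")]
}

#' Write a pair table
#' @param pairs data.frame with drug_a, drug_b and optionally label
#' @param path output file
#' @export
writePairTable <- function(pairs, path) {
  cols <- intersect(c("drug_a", "drug_b", "label"), names(pairs))
  utils::write.table(pairs[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write predictions (probability with 6 decimals)
#' @param pairs data.frame with drug_a, drug_b, probability
#' @param path output file
#' @export
writePredictions <- function(pairs, path) {
  df <- data.frame(drug_a = pairs$drug_a, drug_b = pairs$drug_b,
                   probability = sprintf("%.6f", pairs$probability))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
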