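## SMILES parsing, valence accounting, and serialization for the
## organic-subset grammar: atoms B C N O P S F Cl Br I (aromatic
## b c n o p s), bonds - = # :, branches, ring closures 0-9, bracket
## atoms with H count and charge. Stereochemistry, isotopes and
## multi-fragment strings are out of scope.

.ORGANIC <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.AROMATIC <- c("b", "c", "n", "o", "p", "s")
.HALOGENS <- c("F", "Cl", "Br", "I")

## Default valence sets; multivalent S and P take the smallest valence
## in the set that accommodates the bonds actually drawn.
.VALENCES <- list(B = 3, C = 4, N = 3, O = 2, P = c(3, 5), S = c(2, 4, 6),
                  F = 1, Cl = 1, Br = 1, I = 1)

#' Maximum valence for an element (charge-adjusted)
#'
#' Positive charge on N, O, S or P raises bonding capacity by the
#' charge; negative charge lowers it. Halogens and B are fixed.
#' @noRd
maxValence <- function(symbol, charge = 0) {
  v <- .VALENCES[[symbol]]
  if (is.null(v)) return(Inf)  # "other" elements are not valence-checked
  adj <- if (symbol %in% c("N", "O", "S", "P")) charge else 0
  max(v) + adj
}

#' Smallest allowed valence >= the drawn bond order sum
#' @noRd
targetValence <- function(symbol, charge, bondSum) {
  v <- .VALENCES[[symbol]]
  if (is.null(v)) return(ceiling(bondSum))
  adj <- if (symbol %in% c("N", "O", "S", "P")) charge else 0
  v <- v + adj
  ok <- v[v >= ceiling(bondSum - 1e-9)]
  if (length(ok) == 0) max(v) else min(ok)
}

#' Sum of bond orders incident to each atom (aromatic = 1.5)
#' @noRd
bondOrderSums <- function(atoms, bonds) {
  s <- numeric(nrow(atoms))
  if (nrow(bonds) > 0) {
    for (k in seq_len(nrow(bonds))) {
      s[bonds$a[k]] <- s[bonds$a[k]] + bonds$order[k]
      s[bonds$b[k]] <- s[bonds$b[k]] + bonds$order[k]
    }
  }
  s
}

#' Effective valence consumption per atom.
#'
#' Non-aromatic bonds count at face order. An atom's k aromatic bonds
#' consume k+1 valence units (one formal double bond within the ring)
#' when the element accommodates it, else k (pyrrole-type N, furan-type
#' O/S contribute a lone pair instead).
#' @noRd
effectiveBondSums <- function(atoms, bonds) {
  n <- nrow(atoms)
  sNa <- numeric(n)
  kAr <- integer(n)
  if (nrow(bonds) > 0) {
    for (k in seq_len(nrow(bonds))) {
      for (i in c(bonds$a[k], bonds$b[k])) {
        if (bonds$order[k] == 1.5) kAr[i] <- kAr[i] + 1L
        else sNa[i] <- sNa[i] + bonds$order[k]
      }
    }
  }
  s <- numeric(n)
  for (i in seq_len(n)) {
    cAr <- if (kAr[i] > 0) kAr[i] + 1L else 0L
    mv <- maxValence(atoms$symbol[i], atoms$charge[i])
    h <- if (is.na(atoms$nH[i])) 0L else atoms$nH[i]
    if (sNa[i] + cAr + h > mv && kAr[i] > 0) cAr <- kAr[i]
    s[i] <- sNa[i] + cAr
  }
  s
}

#' Indices of atoms whose bonds + implicit hydrogens exceed valence
#' @noRd
valenceViolations <- function(graph) {
  atoms <- graph@atoms
  if (nrow(atoms) == 0) return(integer(0))
  bs <- effectiveBondSums(atoms, graph@bonds)
  bad <- integer(0)
  for (i in seq_len(nrow(atoms))) {
    mv <- maxValence(atoms$symbol[i], atoms$charge[i])
    if (bs[i] + atoms$nH[i] > mv + 1e-9) bad <- c(bad, i)
  }
  bad
}

.tokenizeSmiles <- function(smiles) {
  chars <- strsplit(smiles, "")[[1]]
  toks <- list()
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop(sprintf("SMILES parse error at position %d: unclosed '['", i))
      toks[[length(toks) + 1L]] <- list(type = "bracket",
                                        text = paste(chars[i:j], collapse = ""),
                                        pos = i)
      i <- j + 1L
    } else if (ch %in% c("C", "B") && i < n && chars[i + 1L] %in% c("l", "r") &&
               paste0(ch, chars[i + 1L]) %in% c("Cl", "Br")) {
      toks[[length(toks) + 1L]] <- list(type = "atom",
                                        text = paste0(ch, chars[i + 1L]), pos = i)
      i <- i + 2L
    } else if (ch %in% .ORGANIC || ch %in% .AROMATIC) {
      toks[[length(toks) + 1L]] <- list(type = "atom", text = ch, pos = i)
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":")) {
      toks[[length(toks) + 1L]] <- list(type = "bond", text = ch, pos = i)
      i <- i + 1L
    } else if (ch %in% c("(", ")")) {
      toks[[length(toks) + 1L]] <- list(type = ch, text = ch, pos = i)
      i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      toks[[length(toks) + 1L]] <- list(type = "ring", text = ch, pos = i)
      i <- i + 1L
    } else {
      stop(sprintf("SMILES parse error at position %d: unexpected character '%s'",
                   i, ch))
    }
  }
  toks
}

.parseBracket <- function(text, pos) {
  body <- substr(text, 2, nchar(text) - 1)
  m <- regmatches(body, regexec(
    "^([A-IK-Za-ik-z][a-z]?)(H[0-9]?)?([+-][0-9]?|\\+\\+|--)?$", body))[[1]]
  if (length(m) == 0 || m[2] == "") {
    stop(sprintf("SMILES parse error at position %d: unsupported bracket atom '%s'",
                 pos, text))
  }
  sym <- m[2]
  aromatic <- sym %in% .AROMATIC
  if (aromatic) sym <- toupper(sym)
  hTxt <- m[3]
  nH <- if (hTxt == "") 0L else if (hTxt == "H") 1L else
    as.integer(substr(hTxt, 2, nchar(hTxt)))
  cTxt <- m[4]
  charge <- 0L
  if (cTxt != "") {
    if (cTxt %in% c("+", "-")) {
      charge <- if (cTxt == "+") 1L else -1L
    } else if (cTxt %in% c("++", "--")) {
      charge <- if (cTxt == "++") 2L else -2L
    } else {
      charge <- as.integer(substr(cTxt, 2, nchar(cTxt)))
      if (substr(cTxt, 1, 1) == "-") charge <- -charge
    }
  }
  list(symbol = sym, aromatic = aromatic, nH = nH, charge = charge,
       explicitH = TRUE)
}

#' Parse a SMILES string into a molecular graph
#'
#' Supports the organic subset (B, C, N, O, P, S, F, Cl, Br, I), aromatic
#' lowercase atoms, bond symbols \code{- = # :}, branches, single-digit
#' ring closures and bracket atoms with hydrogen count and formal
#' charge. Aromatic bonds are perceived between aromatic atoms that
#' share a ring; implicit hydrogens are assigned from standard valences
#' (S and P are multivalent). The result satisfies all
#' \linkS4class{MolecularGraph} invariants, including the valence table;
#' a violation raises an error naming the offending atom.
#'
#' @param smiles a single SMILES string.
#' @return a \linkS4class{MolecularGraph}; atoms in SMILES reading order.
#' @examples
#' g <- parseSmiles("CC(=O)O")   # acetic acid
#' numAtoms(g)                   # 4 heavy atoms
#' @export
parseSmiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || nchar(smiles) == 0) {
    stop("SMILES parse error: input must be one non-empty string")
  }
  toks <- .tokenizeSmiles(smiles)
  atoms <- list()
  bonds <- list()
  prev <- NA_integer_
  pending <- NA_character_
  stack <- integer(0)
  ringOpen <- list()  # digit -> list(atom, order, pos)

  addAtom <- function(rec) {
    atoms[[length(atoms) + 1L]] <<- rec
    length(atoms)
  }
  addBond <- function(a, b, sym, pos) {
    if (a == b) stop(sprintf("SMILES parse error at position %d: self bond", pos))
    order <- switch(ifelse(is.na(sym), "implicit", sym),
                    "-" = 1, "=" = 2, "#" = 3, ":" = 1.5,
                    "implicit" = if (atoms[[a]]$aromatic &&
                                     atoms[[b]]$aromatic) 1.5 else 1)
    bonds[[length(bonds) + 1L]] <<- list(a = a, b = b, order = order)
  }

  for (tk in toks) {
    if (tk$type == "atom") {
      txt <- tk$text
      aromatic <- txt %in% .AROMATIC
      sym <- if (aromatic) toupper(txt) else txt
      idx <- addAtom(list(symbol = sym, aromatic = aromatic, nH = NA_integer_,
                          charge = 0L, explicitH = FALSE))
      if (!is.na(prev)) addBond(prev, idx, pending, tk$pos)
      prev <- idx
      pending <- NA_character_
    } else if (tk$type == "bracket") {
      rec <- .parseBracket(tk$text, tk$pos)
      idx <- addAtom(rec)
      if (!is.na(prev)) addBond(prev, idx, pending, tk$pos)
      prev <- idx
      pending <- NA_character_
    } else if (tk$type == "bond") {
      pending <- tk$text
    } else if (tk$type == "(") {
      if (is.na(prev)) {
        stop(sprintf("SMILES parse error at position %d: branch before any atom",
                     tk$pos))
      }
      stack <- c(stack, prev)
    } else if (tk$type == ")") {
      if (length(stack) == 0) {
        stop(sprintf("SMILES parse error at position %d: unmatched ')'", tk$pos))
      }
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
    } else if (tk$type == "ring") {
      if (is.na(prev)) {
        stop(sprintf("SMILES parse error at position %d: ring digit before any atom",
                     tk$pos))
      }
      d <- tk$text
      if (is.null(ringOpen[[d]])) {
        ringOpen[[d]] <- list(atom = prev, order = pending, pos = tk$pos)
      } else {
        open <- ringOpen[[d]]
        sym <- if (!is.na(open$order)) open$order else pending
        addBond(open$atom, prev, sym, tk$pos)
        ringOpen[[d]] <- NULL
      }
      pending <- NA_character_
    }
  }
  if (length(stack) > 0) stop("SMILES parse error: unclosed branch '('")
  openDigits <- names(ringOpen)[!vapply(ringOpen, is.null, TRUE)]
  if (length(openDigits) > 0) {
    stop(sprintf("SMILES parse error at position %d: unclosed ring closure %s",
                 ringOpen[[openDigits[1]]]$pos, openDigits[1]))
  }

  n <- length(atoms)
  atomDf <- data.frame(
    symbol = vapply(atoms, `[[`, "", "symbol"),
    charge = vapply(atoms, function(a) as.integer(a$charge), 1L),
    aromatic = vapply(atoms, `[[`, TRUE, "aromatic"),
    nH = vapply(atoms, function(a) as.integer(a$nH), 1L),
    stringsAsFactors = FALSE
  )
  bondDf <- if (length(bonds) > 0) {
    data.frame(
      a = vapply(bonds, function(x) as.integer(x$a), 1L),
      b = vapply(bonds, function(x) as.integer(x$b), 1L),
      order = vapply(bonds, function(x) as.numeric(x$order), 1)
    )
  } else {
    data.frame(a = integer(0), b = integer(0), order = numeric(0))
  }
  explicitH <- vapply(atoms, `[[`, TRUE, "explicitH")
  buildGraph(atomDf, bondDf, smiles = smiles, explicitH = explicitH)
}

#' Assemble and validate a MolecularGraph from atom/bond tables
#'
#' Perceives ring membership, demotes aromatic bonds outside rings to
#' single bonds, assigns implicit hydrogens where not explicit, computes
#' degree and adjacency, and enforces the valence table.
#' @noRd
buildGraph <- function(atomDf, bondDf, smiles = "", explicitH = NULL,
                       maskFlags = NULL) {
  n <- nrow(atomDf)
  m <- nrow(bondDf)
  if (is.null(explicitH)) explicitH <- !is.na(atomDf$nH)

  inRingBond <- rep(FALSE, m)
  if (m > 0) {
    ig <- igraph::graph_from_edgelist(cbind(bondDf$a, bondDf$b),
                                      directed = FALSE)
    if (igraph::vcount(ig) < n) {
      ig <- igraph::add_vertices(ig, n - igraph::vcount(ig))
    }
    br <- igraph::bridges(ig)
    inRingBond <- !(seq_len(m) %in% as.integer(br))
    ## aromatic marks outside rings degrade to single bonds
    fix <- which(bondDf$order == 1.5 & !inRingBond)
    if (length(fix) > 0) bondDf$order[fix] <- 1
  }
  bondDf$aromatic <- bondDf$order == 1.5
  bondDf$inRing <- inRingBond

  atomInRing <- rep(FALSE, n)
  if (m > 0) {
    ring <- which(inRingBond)
    atomInRing[unique(c(bondDf$a[ring], bondDf$b[ring]))] <- TRUE
  }
  ## an aromatic flag off-ring is meaningless; drop it
  atomDf$aromatic <- atomDf$aromatic & atomInRing

  bs <- effectiveBondSums(atomDf, bondDf)
  for (i in seq_len(n)) {
    if (!explicitH[i]) {
      tv <- targetValence(atomDf$symbol[i], atomDf$charge[i], bs[i])
      atomDf$nH[i] <- as.integer(max(0, floor(tv - bs[i] + 1e-9)))
    }
    mv <- maxValence(atomDf$symbol[i], atomDf$charge[i])
    if (bs[i] + atomDf$nH[i] > mv + 1e-9) {
      stop(sprintf(
        "chemistry error: valence exceeded at atom %d (%s: bonds %.1f + %dH > %s)",
        i, atomDf$symbol[i], bs[i], atomDf$nH[i], mv))
    }
  }

  deg <- integer(n)
  A <- matrix(0, n, n)
  if (m > 0) {
    for (k in seq_len(m)) {
      A[bondDf$a[k], bondDf$b[k]] <- 1
      A[bondDf$b[k], bondDf$a[k]] <- 1
    }
    deg <- as.integer(rowSums(A))
  }
  atomDf$degree <- deg
  atomDf$inRing <- atomInRing
  if (is.null(maskFlags)) maskFlags <- rep(FALSE, n)

  new("MolecularGraph",
      atoms = atomDf, bonds = bondDf, adjacency = A,
      atomFeatures = matrix(0, 0, 0), bondFeatures = matrix(0, 0, 0),
      smiles = smiles, maskFlags = maskFlags)
}

#' Serialize a molecular graph back to SMILES
#'
#' Depth-first writer with ring-closure digits. Bracket atoms are
#' emitted where charge or a non-default hydrogen count requires them;
#' masked atoms are written as \code{*}. Round-tripping through
#' \code{\link{parseSmiles}} preserves atom and bond counts (atom order
#' may differ for branched molecules).
#'
#' @param graph a \linkS4class{MolecularGraph}.
#' @return a SMILES string.
#' @export
writeSmiles <- function(graph) {
  n <- numAtoms(graph)
  if (n == 0) return("")
  atoms <- graph@atoms
  bonds <- graph@bonds
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    adj[[bonds$a[k]]] <- c(adj[[bonds$a[k]]], k)
    adj[[bonds$b[k]]] <- c(adj[[bonds$b[k]]], k)
  }
  other <- function(k, i) if (bonds$a[k] == i) bonds$b[k] else bonds$a[k]

  bondSym <- function(k) {
    o <- bonds$order[k]
    if (o == 2) "=" else if (o == 3) "#" else ""
  }
  atomTxt <- function(i) {
    if (graph@maskFlags[i]) return("*")
    sym <- atoms$symbol[i]
    base <- if (atoms$aromatic[i]) tolower(sym) else sym
    needBracket <- atoms$charge[i] != 0
    if (!needBracket && sym %in% names(.VALENCES)) {
      ## would the reader infer the same H count?
      ks <- adj[[i]]
      sNa <- sum(bonds$order[ks][bonds$order[ks] != 1.5])
      kAr <- sum(bonds$order[ks] == 1.5)
      cAr <- if (kAr > 0) kAr + 1L else 0L
      if (sNa + cAr > maxValence(sym, 0L) && kAr > 0) cAr <- kAr
      bs <- sNa + cAr
      tv <- targetValence(sym, 0L, bs)
      impl <- as.integer(max(0, floor(tv - bs + 1e-9)))
      if (impl != atoms$nH[i]) needBracket <- TRUE
    }
    if (!needBracket && !(sym %in% .ORGANIC)) needBracket <- TRUE
    if (!needBracket) return(base)
    h <- if (atoms$nH[i] == 0) "" else if (atoms$nH[i] == 1) "H" else
      paste0("H", atoms$nH[i])
    ch <- atoms$charge[i]
    cs <- if (ch == 0) "" else if (ch == 1) "+" else if (ch == -1) "-" else
      if (ch > 0) paste0("+", ch) else paste0("-", abs(ch))
    paste0("[", base, h, cs, "]")
  }

  ## Pass 1: DFS spanning forest. Tree edges get rendered inline; each
  ## back edge gets a ring-closure digit attached to both endpoints.
  m <- nrow(bonds)
  visited <- rep(FALSE, n)
  treeChild <- vector("list", n)   # per atom: bond indices to children
  ringMark <- vector("list", n)    # per atom: closure strings like "=1"
  backEdge <- rep(FALSE, max(1L, m))
  usedBond <- rep(FALSE, max(1L, m))
  nextDigit <- 0L
  roots <- integer(0)

  for (root in seq_len(n)) {
    if (visited[root]) next
    roots <- c(roots, root)
    stack <- list(root)
    visited[root] <- TRUE
    while (length(stack) > 0) {
      i <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (k in adj[[i]]) {
        if (usedBond[k]) next
        j <- other(k, i)
        if (!visited[j]) {
          usedBond[k] <- TRUE
          visited[j] <- TRUE
          treeChild[[i]] <- c(treeChild[[i]], k)
          stack[[length(stack) + 1L]] <- j
        } else {
          usedBond[k] <- TRUE
          backEdge[k] <- TRUE
          nextDigit <- nextDigit + 1L
          if (nextDigit > 9L) stop("SMILES writer: more than 9 ring closures")
          d <- as.character(nextDigit)
          ringMark[[i]] <- c(ringMark[[i]], paste0(bondSym(k), d))
          ringMark[[j]] <- c(ringMark[[j]], d)
        }
      }
    }
  }

  ## Pass 2: render the forest recursively.
  render <- function(i) {
    out <- paste0(atomTxt(i), paste(ringMark[[i]], collapse = ""))
    ks <- treeChild[[i]]
    for (ci in seq_along(ks)) {
      k <- ks[ci]
      sub <- paste0(bondSym(k), render(other(k, i)))
      out <- if (ci < length(ks)) paste0(out, "(", sub, ")")
             else paste0(out, sub)
    }
    out
  }
  paste(vapply(roots, render, ""), collapse = ".")
}
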