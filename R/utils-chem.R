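# Low-level chemistry helpers built on ChemmineR/ChemmineOB (Open Babel).
# All structure text in and out of this file is SMILES; canonical forms and
# InChIKeys come from Open Babel so they agree with what `openbabel` itself
# would emit.

.canonCache <- new.env(parent = emptyenv())
.ikeyCache <- new.env(parent = emptyenv())
.graphCache <- new.env(parent = emptyenv())
.fragCache <- new.env(parent = emptyenv())

.obStrip <- function(x) sub("[\t ].*$", "", x)

.obConvertOne <- function(smiles, to) {
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", to, smiles)),
    error = function(e) ""
  )
  out <- .obStrip(sub("\n$", "", out))
  if (!length(out) || is.na(out) || !nzchar(out)) NA_character_ else out
}

.obConvertMany <- function(smiles, to, cache) {
  out <- rep(NA_character_, length(smiles))
  if (!length(smiles)) return(out)
  key <- smiles
  hit <- vapply(key, function(k) !is.na(k) && nzchar(k) &&
                  !is.null(cache[[k]]), logical(1))
  out[hit] <- vapply(key[hit], function(k) cache[[k]], character(1))
  miss <- which(!hit & !is.na(key) & nzchar(key))
  if (length(miss)) {
    umiss <- unique(key[miss])
    # batch first: Open Babel drops failed molecules from batch output, so
    # the batch result is only trusted when the line count is preserved
    res <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat(
        "SMI", to, paste(umiss, collapse = "\n"))),
      error = function(e) ""
    )
    lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
    if (length(lines) == length(umiss)) {
      vals <- .obStrip(lines)
      vals[!nzchar(vals)] <- NA_character_
    } else {
      vals <- vapply(umiss, .obConvertOne, character(1), to = to)
    }
    for (i in seq_along(umiss)) cache[[umiss[i]]] <- vals[i]
    out[miss] <- vals[match(key[miss], umiss)]
  }
  out
}

#' Canonical SMILES via Open Babel
#'
#' Converts SMILES strings to Open Babel canonical SMILES. Unparsable input
#' yields `NA`. Results are memoised for the session.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES, `NA` where parsing failed.
#' @examples
#' canonicalSmiles(c("OCC", "CCO"))  # both "CCO"
#' @export
canonicalSmiles <- function(smiles) {
  .obConvertMany(as.character(smiles), "CAN", .canonCache)
}

#' InChIKey via Open Babel
#'
#' Standard InChIKey of a structure, used as the deduplication key: two
#' inputs share a key exactly when their standardized structures are
#' identical.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of InChIKeys, `NA` where parsing failed.
#' @examples
#' inchikey("CCO")
#' @export
inchikey <- function(smiles) {
  .obConvertMany(as.character(smiles), "INCHIKEY", .ikeyCache)
}

# elements allowed in retained organics; anything else is metal/metalloid
# territory and triggers inorganic/organometallic rejection. Si is kept
# because chlorosilanes are a packaged irritation alert class.
.ORGANIC_ELEMENTS <- c("H", "B", "C", "N", "O", "F", "Si", "P", "S",
                       "Cl", "Se", "Br", "I")

# SDF charge-code field (atom block column "C6"): 1..3 = +3..+1, 5..7 = -1..-3
.chargeFromCode <- function(code) {
  ifelse(code %in% 1:3, 4L - as.integer(code),
         ifelse(code %in% 5:7, 4L - as.integer(code), 0L))
}

.singleAtomGraph <- function(smi) {
  m <- regmatches(smi, regexec(
    "^\\[?([A-Z][a-z]?)(H[0-9]*)?([+-][0-9]?)?\\]?$", smi))[[1]]
  if (!length(m)) return(NULL)
  chg <- 0L
  if (nzchar(m[4])) {
    sign <- if (substr(m[4], 1, 1) == "+") 1L else -1L
    mag <- if (nchar(m[4]) > 1) as.integer(substr(m[4], 2, 2)) else 1L
    chg <- sign * mag
  }
  list(n = 1L, element = m[2], charge = chg, aromatic = FALSE,
       bonds = data.frame(from = integer(0), to = integer(0),
                          order = integer(0), aromatic = logical(0),
                          ring = logical(0)))
}

# Scan a SMILES string for atom tokens. Returns one row per heavy atom in
# order of appearance (which Open Babel preserves when converting to a
# connection table): the token text, whether it is written aromatic
# (lowercase), and the string position after which a branch may be
# inserted (i.e. after any ring-closure digits).
.smilesAtomTokens <- function(smi) {
  chars <- strsplit(smi, "")[[1]]
  n <- length(chars)
  pos <- integer(0); token <- character(0); arom <- logical(0)
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    tok <- NULL
    ar <- FALSE
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      tok <- paste(chars[i:j], collapse = "")
      ar <- grepl("^\\[[0-9]*[a-z]", tok)
      i <- j
    } else if (ch %in% c("C", "B") && i < n &&
               chars[i + 1] %in% c("l", "r")) {
      tok <- paste0(ch, chars[i + 1])
      i <- i + 1L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      tok <- ch
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      tok <- ch
      ar <- TRUE
    }
    if (!is.null(tok)) {
      j <- i
      while (j < n && (chars[j + 1] %in% as.character(0:9) ||
                       chars[j + 1] == "%"))
        j <- j + 1L
      pos <- c(pos, j)
      token <- c(token, tok)
      arom <- c(arom, ar)
      i <- j
    }
    i <- i + 1L
  }
  data.frame(pos = pos, token = token, aromatic = arom,
             stringsAsFactors = FALSE)
}

# Parse one SMILES into an internal molecular graph: heavy atoms with
# element / formal charge / aromaticity, bonds with order, aromaticity and
# ring membership. Ring membership comes from ChemmineR ring perception;
# atom aromaticity is read from the (canonical) SMILES text itself, where
# Open Babel writes aromatic atoms lowercase — ChemmineR's own aromaticity
# flag is a 2D-planarity heuristic that marks saturated rings aromatic.
.molGraph <- function(smiles) {
  key <- smiles
  g <- .graphCache[[key]]
  if (!is.null(g)) return(g)
  g <- .molGraphImpl(smiles)
  .graphCache[[key]] <- g
  g
}

.molGraphImpl <- function(smiles) {
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(c(m = smiles))),
    error = function(e) NULL
  )
  ok <- !is.null(sdf) && length(sdf) == 1 &&
    isTRUE(tryCatch(ChemmineR::validSDF(sdf), error = function(e) FALSE))
  if (!ok) return(.singleAtomGraph(canonicalSmiles(smiles)))
  mol <- sdf[[1]]
  ab <- ChemmineR::atomblock(mol)
  bb <- ChemmineR::bondblock(mol)
  element <- sub("_.*$", "", rownames(ab))
  charge <- .chargeFromCode(if ("C6" %in% colnames(ab)) ab[, "C6"] else
                              rep(0, nrow(ab)))
  n <- nrow(ab)
  bonds <- data.frame(from = as.integer(bb[, 1]), to = as.integer(bb[, 2]),
                      order = as.integer(bb[, 3]))
  rawRings <- tryCatch(
    suppressWarnings(ChemmineR::rings(mol, type = "all", arom = FALSE)),
    error = function(e) NULL
  )
  toks <- .smilesAtomTokens(smiles)
  aromAtom <- if (nrow(toks) == n) toks$aromatic else rep(FALSE, n)
  bondKey <- function(i, j) paste(pmin(i, j), pmax(i, j))
  ringBonds <- character(0)
  if (length(rawRings)) {
    for (k in seq_along(rawRings)) {
      idx <- as.integer(sub("^.*_", "", rawRings[[k]]))
      pairs <- cbind(idx, c(idx[-1], idx[1]))
      ringBonds <- c(ringBonds, bondKey(pairs[, 1], pairs[, 2]))
    }
  }
  keys <- bondKey(bonds$from, bonds$to)
  inRing <- keys %in% ringBonds
  bonds$aromatic <- (inRing & aromAtom[bonds$from] & aromAtom[bonds$to]) |
    bonds$order == 4L
  bonds$ring <- inRing | bonds$aromatic
  list(n = n, element = element, charge = as.integer(charge),
       aromatic = aromAtom, bonds = bonds)
}

.adjList <- function(g) {
  adj <- vector("list", g$n)
  for (i in seq_len(nrow(g$bonds))) {
    f <- g$bonds$from[i]; t <- g$bonds$to[i]
    adj[[f]] <- c(adj[[f]], t)
    adj[[t]] <- c(adj[[t]], f)
  }
  adj
}

# SMILES tokens for one atom of the internal graph, as a substructure query:
# aromatic atoms lowercase, charges kept, no hydrogen counts added.
.atomToken <- function(g, i) {
  el <- g$element[i]
  ar <- g$aromatic[i]
  chg <- g$charge[i]
  sym <- if (ar) tolower(el) else el
  needBracket <- chg != 0L ||
    !(el %in% c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I"))
  if (!needBracket) return(sym)
  cs <- if (chg == 0L) "" else if (chg == 1L) "+" else if (chg == -1L) "-"
        else if (chg > 0) paste0("+", chg) else paste0("-", abs(chg))
  paste0("[", sym, cs, "]")
}

.bondToken <- function(g, bondRow, bothAromaticAtoms) {
  if (bondRow$aromatic) return("")
  switch(as.character(bondRow$order),
         "1" = if (bothAromaticAtoms) "-" else "",
         "2" = "=",
         "3" = "#",
         "")
}

# Write a SMILES string for the subgraph induced by `atoms` (integer ids).
# DFS spanning tree with ring-closure digits for back edges. The result is
# raw (non-canonical); canonicalise with canonicalSmiles().
.fragmentSmiles <- function(g, atoms, root = NULL) {
  atoms <- sort(unique(as.integer(atoms)))
  if (!is.null(root)) {
    stopifnot(root %in% atoms)
    atoms <- c(root, setdiff(atoms, root))
  }
  if (length(atoms) == 1L) return(.atomToken(g, atoms))
  inS <- logical(g$n); inS[atoms] <- TRUE
  bidx <- which(inS[g$bonds$from] & inS[g$bonds$to])
  sub <- g$bonds[bidx, , drop = FALSE]
  adj <- list()
  for (a in atoms) adj[[as.character(a)]] <- integer(0)
  for (i in seq_len(nrow(sub))) {
    f <- sub$from[i]; t <- sub$to[i]
    adj[[as.character(f)]] <- c(adj[[as.character(f)]], i)
    adj[[as.character(t)]] <- c(adj[[as.character(t)]], i)
  }
  visited <- logical(g$n)
  usedBond <- logical(nrow(sub))
  closures <- list()     # per atom: list of closure strings
  nextDigit <- 0L
  for (a in atoms) closures[[as.character(a)]] <- character(0)
  # first pass: assign ring-closure digits for back edges via iterative DFS
  order <- integer(0)
  parentBond <- rep(NA_integer_, g$n)
  stack <- atoms[1]
  visited[atoms[1]] <- TRUE
  treeChildren <- list()
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    order <- c(order, v)
    for (bi in adj[[as.character(v)]]) {
      if (usedBond[bi]) next
      w <- if (sub$from[bi] == v) sub$to[bi] else sub$from[bi]
      if (!visited[w]) {
        usedBond[bi] <- TRUE
        visited[w] <- TRUE
        parentBond[w] <- bi
        treeChildren[[as.character(v)]] <-
          c(treeChildren[[as.character(v)]], w)
        stack <- c(stack, w)
      } else {
        usedBond[bi] <- TRUE   # back edge -> ring closure
        nextDigit <- nextDigit + 1L
        dig <- if (nextDigit <= 9L) as.character(nextDigit)
               else paste0("%", nextDigit)
        btok <- .bondToken(g, sub[bi, ], g$aromatic[v] && g$aromatic[w])
        closures[[as.character(v)]] <-
          c(closures[[as.character(v)]], paste0(btok, dig))
        closures[[as.character(w)]] <-
          c(closures[[as.character(w)]], dig)
      }
    }
  }
  # second pass: emit SMILES by recursive write over the spanning tree
  emit <- function(v) {
    out <- paste0(.atomToken(g, v),
                  paste(closures[[as.character(v)]], collapse = ""))
    kids <- treeChildren[[as.character(v)]]
    if (length(kids)) {
      parts <- character(length(kids))
      for (k in seq_along(kids)) {
        w <- kids[k]
        bi <- parentBond[w]
        btok <- .bondToken(g, sub[bi, ], g$aromatic[v] && g$aromatic[w])
        parts[k] <- paste0(btok, emit(w))
      }
      out <- paste0(out,
                    paste0(vapply(parts[-length(parts)],
                                  function(p) paste0("(", p, ")"),
                                  character(1)), collapse = ""),
                    parts[length(parts)])
    }
    out
  }
  emit(atoms[1])
}

# Rigid components: contract every bond that the fragmentation scheme may
# not break (ring bonds, aromatic bonds, double/triple bonds). Fragments are
# unions of rigid components connected by breakable acyclic single bonds.
.rigidComponents <- function(g) {
  parent <- seq_len(g$n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(nrow(g$bonds))) {
    b <- g$bonds[i, ]
    if (b$ring || b$aromatic || b$order != 1L) {
      rf <- find(b$from); rt <- find(b$to)
      if (rf != rt) parent[rt] <- rf
    }
  }
  comp <- vapply(seq_len(g$n), find, integer(1))
  match(comp, unique(comp))
}

# ESU-style enumeration of all connected node subsets of a small weighted
# graph, pruned so total weight never exceeds maxw. Returns list of integer
# vectors. Each connected subset is produced exactly once.
.connectedSubsets <- function(adj, weight, maxw) {
  n <- length(adj)
  res <- list()
  for (root in seq_len(n)) {
    if (weight[root] > maxw) next
    extend <- function(S, wS, ext) {
      res[[length(res) + 1L]] <<- S
      while (length(ext)) {
        v <- ext[1]
        ext <- ext[-1]
        if (wS + weight[v] <= maxw) {
          newExt <- ext
          for (u in adj[[v]]) {
            if (u > root && !(u %in% S) && !(u %in% newExt) && u != v) {
              inNS <- any(vapply(S, function(s) u %in% adj[[s]], logical(1)))
              if (!inNS) newExt <- c(newExt, u)
            }
          }
          extend(c(S, v), wS + weight[v], newExt)
        }
      }
    }
    ext0 <- adj[[root]][adj[[root]] > root]
    extend(root, weight[root], unique(ext0))
  }
  res
}
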