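# Shared fixtures and oracles, all built in code.

# Brute-force fragment oracle: enumerate every atom subset of a small
# molecule, keep those that are connected and whose boundary bonds are all
# acyclic single non-aromatic bonds, and canonicalise. Independent of the
# package's contracted-graph enumeration path.
bruteFragments <- function(smiles, minAtoms = 4L, maxAtoms = 20L) {
  g <- respiscreen:::.molGraph(smiles)
  n <- g$n
  if (is.null(g) || n < minAtoms) return(character(0))
  stopifnot(n <= 12)  # oracle is exponential by design
  bonds <- g$bonds
  out <- character(0)
  for (mask in seq_len(2^n - 1)) {
    atoms <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(atoms) < minAtoms || length(atoms) > maxAtoms) next
    inS <- logical(n); inS[atoms] <- TRUE
    # connectivity by flood fill over induced bonds
    reach <- logical(n); reach[atoms[1]] <- TRUE
    repeat {
      grew <- FALSE
      for (b in seq_len(nrow(bonds))) {
        f <- bonds$from[b]; t <- bonds$to[b]
        if (inS[f] && inS[t]) {
          if (reach[f] && !reach[t]) { reach[t] <- TRUE; grew <- TRUE }
          if (reach[t] && !reach[f]) { reach[f] <- TRUE; grew <- TRUE }
        }
      }
      if (!grew) break
    }
    if (!all(reach[atoms])) next
    boundary <- xor(inS[bonds$from], inS[bonds$to])
    cuttable <- bonds$order == 1L & !bonds$ring & !bonds$aromatic
    if (any(boundary & !cuttable)) next
    out <- c(out, respiscreen:::.fragmentSmiles(g, atoms))
  }
  if (!length(out)) return(character(0))
  res <- unique(canonicalSmiles(unique(out)))
  res[!is.na(res)]
}

# small labeled set: nA actives carrying `motif`, nI motif-free inactives
toyPlantedSet <- function(motif = "C(=O)OC(=O)", nA = 5, nI = 5) {
  tails <- c("C", "CC", "CCC", "CCCC", "C(C)C", "CCCCC", "CC(C)C")
  act <- paste0("CC(=O)OC(=O)", tails[seq_len(nA)])
  if (motif != "C(=O)OC(=O)")
    act <- vapply(seq_len(nA), function(i)
      paste0(substr("CCCCCCC", 1, i + 1), "(", motif, ")C"), character(1))
  ina <- c("CCCCCC", "CCOCC", "CCCOC", "CC(C)CC", "CCCCO", "CCCCCCC",
           "CCOCCC")[seq_len(nI)]
  MoleculeSet(data.frame(
    record_id = sprintf("t%02d", seq_len(nA + nI)),
    smiles = canonicalSmiles(c(act, ina)),
    label = rep(c("active", "inactive"), c(nA, nI))))
}

# tiny consensus model fit on a separable set; cached per session so the
# screening tests do not refit repeatedly
toyModel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      x <- generateFeatureSeparableSet(60, 1, seed = 101)
      cache <<- trainConsensus(
        x, specs = list(modelSpec("fp2", "rf"), modelSpec("maccs", "xgb")),
        seed = 101)
    }
    cache
  }
})
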