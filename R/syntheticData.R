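# Synthetic labeled chemical sets with planted alert substructures.
# Actives are alert-free scaffolds with a motif grafted through one single
# bond, so the motif is guaranteed to survive as a subgraph and ground
# truth is exact; inactives are motif-free scaffolds. Controlled noise
# plants nothing in a fraction of actives (planting noise) or a motif in
# a fraction of inactives (decoy noise).

#' Default decoy scaffold pool
#'
#' Thirty small alert-free hydrocarbons and aliphatic ethers (C/O only,
#' no carbonyls, amines or halogens), verified in the test suite to match
#' none of the packaged alert patterns.
#'
#' @param ethers if `FALSE`, only pure hydrocarbons are returned —
#'   useful when planting oxygen- or nitrogen-containing motifs whose
#'   graft junction could otherwise create incidental ether-adjacent
#'   substructures.
#' @return character vector of SMILES.
#' @export
defaultScaffolds <- function(ethers = TRUE) {
  hydro <- c("CCCC", "CCCCC", "CCCCCC", "CCCCCCC", "CCCCCCCC",
             "CC(C)CC", "CC(C)CCC", "CCC(C)CC", "CCC(CC)CC", "CC(C)C(C)C",
             "C1CCCCC1", "CC1CCCCC1", "CCC1CCCCC1", "C1CCCC1",
             "CC1CCCC1", "CC1CCC(C)CC1", "C1CCCCCC1", "CCCC1CCCC1",
             "CC(C)C1CCCCC1", "CCCCC1CCCCC1")
  eth <- c("CCOCC", "CCCOC", "CCOCCC", "COCCOC", "CCOC(C)C",
           "CCCCOCC", "CC(C)OC(C)C", "CCCOCCC", "COC1CCCCC1",
           "CCCCCOC")
  if (ethers) c(hydro, eth) else hydro
}

#' Benchmark motif subset
#'
#' Eight packaged alert patterns that are pairwise structurally disjoint
#' (no shared fragment of 4+ heavy atoms), so that planted-alert recovery
#' is well-posed: with overlapping motifs a shared sub-fragment can
#' legitimately cover two motifs' actives at once and ground truth is
#' ambiguous.
#'
#' @return character vector of SMILES patterns.
#' @export
benchmarkMotifs <- function() {
  c("C(=O)OC(=O)", "CN=C=O", "OCC1OC1", "[O-][N+](=O)C",
    "C[Si](Cl)(Cl)", "NCCO", "ClCC(Cl)", "S(=O)(=O)N")
}

#' Generator configuration
#'
#' @param nActive,nInactive class sizes.
#' @param motifPool candidate motif patterns; defaults to the full set of
#'   packaged irritation + sensitization alert patterns.
#' @param motifsPerDataset how many motifs are sampled and planted.
#' @param plantingNoise fraction of actives left motif-free
#'   (`round(plantingNoise * nActive)` molecules).
#' @param decoyNoise fraction of inactives that receive a motif.
#' @param scaffoldPool decoy scaffolds; see [defaultScaffolds()].
#' @param seed integer seed; identical configs give byte-identical
#'   output.
#' @return a `GeneratorConfig` list.
#' @export
generatorConfig <- function(nActive = 40L, nInactive = 40L,
                            motifPool = NULL, motifsPerDataset = 3L,
                            plantingNoise = 0, decoyNoise = 0,
                            scaffoldPool = defaultScaffolds(),
                            seed = 1L) {
  if (is.null(motifPool))
    motifPool <- c(alertRules(alertLibrary("irritation"))$smiles,
                   alertRules(alertLibrary("sensitization"))$smiles)
  stopifnot(plantingNoise >= 0, plantingNoise <= 1,
            decoyNoise >= 0, decoyNoise <= 1,
            motifsPerDataset >= 1, nActive >= 1, nInactive >= 0)
  structure(list(nActive = as.integer(nActive),
                 nInactive = as.integer(nInactive),
                 motifPool = motifPool,
                 motifsPerDataset = as.integer(motifsPerDataset),
                 plantingNoise = plantingNoise, decoyNoise = decoyNoise,
                 scaffoldPool = scaffoldPool, seed = as.integer(seed)),
            class = "GeneratorConfig")
}

# Re-root a motif SMILES at every atom, giving alternative writings whose
# first atom is the graft point.
.motifWritings <- function(motif) {
  g <- .molGraph(motif)
  if (is.null(g)) return(character(0))
  outs <- vapply(seq_len(g$n), function(r)
    .fragmentSmiles(g, seq_len(g$n), root = r), character(1))
  unique(.shiftRingDigits(outs, by = 5L))
}

# shift ring-closure digits 1-4 -> 6-9 (outside brackets) so grafting a
# motif into a scaffold cannot collide with the scaffold's own ring digits
.shiftRingDigits <- function(smiles, by = 5L) {
  vapply(smiles, function(s) {
    chars <- strsplit(s, "")[[1]]
    depth <- 0L
    for (i in seq_along(chars)) {
      ch <- chars[i]
      if (ch == "[") depth <- depth + 1L
      else if (ch == "]") depth <- depth - 1L
      else if (depth == 0L && ch %in% as.character(1:4))
        chars[i] <- as.character(as.integer(ch) + by)
    }
    paste(chars, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# insertion points on scaffold carbons that can accept one more single
# bond (total bond order <= 3), so grafting never creates a 5-valent atom
.attachmentPoints <- function(scaffold) {
  toks <- .smilesAtomTokens(scaffold)
  if (!nrow(toks)) return(integer(0))
  toks$isC <- toks$token == "C"
  g <- .molGraph(scaffold)
  if (is.null(g) || g$n != nrow(toks)) {
    return(toks$pos[toks$isC])
  }
  valence <- numeric(g$n)
  for (i in seq_len(nrow(g$bonds))) {
    o <- if (g$bonds$aromatic[i]) 1.5 else g$bonds$order[i]
    valence[g$bonds$from[i]] <- valence[g$bonds$from[i]] + o
    valence[g$bonds$to[i]] <- valence[g$bonds$to[i]] + o
  }
  ok <- toks$isC & g$element == "C" & !g$aromatic & valence <= 3
  toks$pos[ok]
}

.graft <- function(scaffold, motifWriting, at) {
  paste0(substr(scaffold, 1, at), "(", motifWriting, ")",
         substr(scaffold, at + 1, nchar(scaffold)))
}

# graft `motif` onto `scaffold` at a seed-controlled random attachment,
# validating that the result parses and still contains the motif as a
# substructure; tries all writings x attachment points before giving up
.plantMotif <- function(scaffold, motif, writings) {
  pts <- .attachmentPoints(scaffold)
  if (!length(pts)) return(NA_character_)
  order1 <- sample(length(pts))
  for (p in pts[order1]) {
    for (w in writings) {
      cand <- .graft(scaffold, w, p)
      can <- canonicalSmiles(cand)
      if (is.na(can)) next
      if (.matchesMotif(can, motif)) return(can)
    }
  }
  NA_character_
}

.matchesMotif <- function(smiles, motif) {
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(c(q = smiles))),
    error = function(e) NULL)
  if (is.null(sdf) || !length(sdf)) return(FALSE)
  hit <- tryCatch(
    ChemmineR::smartsSearchOB(sdf, motif, uniqueMatches = TRUE),
    error = function(e) 0)
  any(hit > 0)
}

.decorations <- c("", "C", "CC", "CCC", "C(C)C")

.decorate <- function(scaffold) {
  dec <- sample(.decorations, 1)
  if (!nzchar(dec)) return(scaffold)
  pts <- .attachmentPoints(scaffold)
  if (!length(pts)) return(scaffold)
  cand <- .graft(scaffold, dec, sample(pts, 1))
  can <- canonicalSmiles(cand)
  if (is.na(can)) scaffold else can
}

#' Generate a labeled dataset with planted alert substructures
#'
#' @param config a [generatorConfig()].
#' @return list with `molecules` (a labeled, curation-clean
#'   [MoleculeSet-class]), `manifest` (data.frame: record_id, label,
#'   motif — `NA` for molecules carrying none — and scaffold), and
#'   `motifs` (the sampled motif patterns).
#' @examples
#' d <- generateDataset(generatorConfig(nActive = 4, nInactive = 4,
#'                                      motifsPerDataset = 1, seed = 7))
#' d$manifest
#' @export
generateDataset <- function(config = generatorConfig()) {
  stopifnot(inherits(config, "GeneratorConfig"))
  withr::with_seed(config$seed, .generateDatasetImpl(config))
}

.generateDatasetImpl <- function(config) {
  motifs <- if (length(config$motifPool) <= config$motifsPerDataset)
    config$motifPool else
    sample(config$motifPool, config$motifsPerDataset)
  writings <- lapply(motifs, .motifWritings)
  names(writings) <- motifs
  # scaffolds must be free of every sampled motif, or ground truth breaks
  scafOK <- vapply(config$scaffoldPool, function(s)
    !any(vapply(motifs, function(m) .matchesMotif(s, m), logical(1))),
    logical(1))
  scaffolds <- config$scaffoldPool[scafOK]
  if (!length(scaffolds))
    stop("configuration error: no scaffold is free of the sampled motifs")
  graftable <- vapply(motifs, function(m)
    !is.na(.plantMotif(scaffolds[1], m, writings[[m]])), logical(1))
  if (!all(graftable))
    stop("configuration error: motif(s) not graftable onto any scaffold: ",
         paste(motifs[!graftable], collapse = ", "))
  nA <- config$nActive; nI <- config$nInactive
  nBlank <- round(config$plantingNoise * nA)
  nDecoy <- round(config$decoyNoise * nI)
  motifOfActive <- rep_len(motifs, nA)
  blankIdx <- if (nBlank > 0) sample(nA, nBlank) else integer(0)
  motifOfActive[blankIdx] <- NA_character_
  decoyIdx <- if (nDecoy > 0) sample(nI, nDecoy) else integer(0)
  motifOfInactive <- rep(NA_character_, nI)
  if (length(decoyIdx))
    motifOfInactive[decoyIdx] <- sample(motifs, nDecoy, replace = TRUE)
  build <- function(motif) {
    for (try in seq_len(20L)) {
      sc <- .decorate(sample(scaffolds, 1))
      if (is.na(motif)) {
        out <- canonicalSmiles(sc)
        attr(out, "scaffold") <- sc
        return(out)
      }
      out <- .plantMotif(sc, motif, writings[[motif]])
      if (!is.na(out)) {
        attr(out, "scaffold") <- sc
        return(out)
      }
    }
    stop("configuration error: motif ungraftable: ", motif)
  }
  smiA <- lapply(motifOfActive, build)
  smiI <- lapply(motifOfInactive, build)
  ids <- c(sprintf("act%04d", seq_len(nA)),
           if (nI) sprintf("ina%04d", seq_len(nI)))
  smiles <- c(unlist(lapply(smiA, as.character)),
              unlist(lapply(smiI, as.character)))
  manifest <- data.frame(
    record_id = ids,
    label = c(rep("active", nA), rep("inactive", nI)),
    motif = c(motifOfActive, motifOfInactive),
    scaffold = c(vapply(smiA, attr, character(1), "scaffold"),
                 vapply(smiI, attr, character(1), "scaffold")),
    stringsAsFactors = FALSE)
  mols <- MoleculeSet(data.frame(
    record_id = ids, raw_input = smiles, smiles = smiles,
    dedup_key = inchikey(smiles), label = manifest$label,
    endpoint = "none", provenance = "synthetic",
    stringsAsFactors = FALSE))
  stopifnot(nrow(manifest) == length(mols))
  list(molecules = mols, manifest = manifest, motifs = motifs)
}

#' Generate a feature-separable set for model benchmarking
#'
#' Two structure families — chlorinated aromatics versus aliphatic
#' hydrocarbons/ethers — whose fingerprints are easily told apart. At
#' `separation = 1` every active is drawn from the aromatic family and
#' every inactive from the aliphatic family, so any sane learner
#' separates them; at `separation = 0` the family is a coin flip
#' independent of the label and accuracy collapses to chance.
#'
#' @param n total number of molecules (n/2 per class), at least 20.
#' @param separation value in \[0, 1\].
#' @param seed integer seed.
#' @return a labeled [MoleculeSet-class].
#' @export
generateFeatureSeparableSet <- function(n = 100L, separation = 1,
                                        seed = 1L) {
  stopifnot(n >= 20, separation >= 0, separation <= 1)
  famA <- c("Clc1ccccc1", "Clc1ccccc1Cl", "Clc1ccc(Cl)cc1",
            "ClCc1ccccc1", "Clc1cccc(Cl)c1", "ClCCc1ccccc1",
            "Clc1ccccc1C", "ClCc1ccc(C)cc1", "Cc1ccc(Cl)cc1C",
            "ClCCCc1ccccc1")
  famB <- defaultScaffolds()
  half <- floor(n / 2)
  nTot <- 2L * half
  withr::with_seed(seed, {
    labels <- c(rep("active", half), rep("inactive", nTot - half))
    own <- stats::runif(nTot) < 0.5 + separation / 2
    fam <- ifelse((labels == "active") == own, "A", "B")
    smiles <- vapply(fam, function(f)
      .decorate(sample(if (f == "A") famA else famB, 1)), character(1))
  })
  MoleculeSet(data.frame(
    record_id = sprintf("sep%04d", seq_len(nTot)),
    raw_input = smiles, smiles = canonicalSmiles(smiles),
    dedup_key = NA_character_, label = labels, endpoint = "none",
    provenance = "synthetic-separable", stringsAsFactors = FALSE))
}
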