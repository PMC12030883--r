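# Data-driven structural-alert mining: enumerate substructure fragments of
# every labeled molecule, tabulate per-fragment support, and select alerts
# by precision-ranked greedy covering of the active molecules.
#
# The fragmentation scheme cuts acyclic single non-aromatic bonds only, so
# a fragment is a connected union of "rigid" units (ring systems and
# multiple-bond pairs stay intact). Broken bonds become unconstrained
# attachment points: a fragment matches any molecule that contains it as a
# subgraph.

#' Mining configuration
#'
#' Defaults follow the published mining protocol: fragments of 4-20 heavy
#' atoms occurring in at least 4 active compounds. The precision floor is
#' this package's own selection knob (the original tool's internal
#' criterion is unpublished); 0.8 is the default at which packaged-alert
#' -like precision emerges on synthetic benchmarks, and it is fully
#' configurable.
#'
#' @param minAtoms,maxAtoms heavy-atom bounds for emitted fragments.
#' @param minSupportActive minimum number of active molecules a rule must
#'   match.
#' @param minPrecision minimum fraction of a rule's matches that are
#'   active.
#' @param maxRules optional cap on the number of emitted rules.
#' @return a `MiningConfig` list.
#' @examples
#' miningConfig()
#' @export
miningConfig <- function(minAtoms = 4L, maxAtoms = 20L,
                         minSupportActive = 4L, minPrecision = 0.8,
                         maxRules = Inf) {
  stopifnot(minAtoms >= 1, minAtoms <= maxAtoms, minSupportActive >= 1,
            minPrecision >= 0, minPrecision <= 1)
  structure(list(minAtoms = as.integer(minAtoms),
                 maxAtoms = as.integer(maxAtoms),
                 minSupportActive = as.integer(minSupportActive),
                 minPrecision = minPrecision, maxRules = maxRules),
            class = "MiningConfig")
}

.countHeavyAtoms <- function(smiles) {
  vapply(smiles, function(s) length(.smilesElements(s)), integer(1))
}

#' Enumerate the substructure fragments of one molecule
#'
#' Returns every canonical fragment obtainable by cutting acyclic single
#' bonds (rings and multiple bonds survive intact) whose heavy-atom count
#' lies within the configured bounds. Chemically identical fragments from
#' different molecules canonicalise to the same text.
#'
#' @param smiles a single SMILES string.
#' @param config a [miningConfig()].
#' @return character vector of canonical fragment SMILES (possibly empty).
#' @examples
#' enumerateFragments("CCCCC")  # butyl and pentyl chains
#' @export
enumerateFragments <- function(smiles, config = miningConfig()) {
  stopifnot(length(smiles) == 1)
  key <- paste(smiles, config$minAtoms, config$maxAtoms)
  hit <- .fragCache[[key]]
  if (!is.null(hit)) return(hit)
  res <- .enumerateFragmentsImpl(smiles, config)
  .fragCache[[key]] <- res
  res
}

.enumerateFragmentsImpl <- function(smiles, config) {
  g <- .molGraph(smiles)
  if (is.null(g) || g$n < config$minAtoms) return(character(0))
  comp <- .rigidComponents(g)
  k <- max(comp)
  weight <- tabulate(comp, nbins = k)
  adj <- vector("list", k)
  for (i in seq_len(k)) adj[[i]] <- integer(0)
  for (i in seq_len(nrow(g$bonds))) {
    cf <- comp[g$bonds$from[i]]; ct <- comp[g$bonds$to[i]]
    if (cf != ct) {
      adj[[cf]] <- unique(c(adj[[cf]], ct))
      adj[[ct]] <- unique(c(adj[[ct]], cf))
    }
  }
  subsets <- .connectedSubsets(adj, weight, config$maxAtoms)
  raws <- character(0)
  for (S in subsets) {
    natoms <- sum(weight[S])
    if (natoms < config$minAtoms) next
    atoms <- which(comp %in% S)
    raws <- c(raws, .fragmentSmiles(g, atoms))
  }
  raws <- unique(raws)
  if (!length(raws)) return(character(0))
  out <- unique(canonicalSmiles(raws))
  out[!is.na(out)]
}

#' Tabulate fragment support on a labeled set
#'
#' Counts, for every fragment enumerated from the set, the number of
#' active and inactive molecules containing it (each molecule at most
#' once, however often the fragment occurs inside it). Fragments seen in
#' fewer than `minSupportActive` actives are pruned.
#'
#' @param x a labeled [MoleculeSet-class].
#' @param config a [miningConfig()].
#' @return data.frame with columns `fragment`, `n_active`, `n_inactive`,
#'   `precision`, `size`, sorted by decreasing precision then support.
#' @export
tabulateFragments <- function(x, config = miningConfig()) {
  idx <- .fragmentIndex(x, config)
  stats <- .fragmentStats(idx)
  stats <- stats[stats$n_active >= config$minSupportActive, , drop = FALSE]
  stats[order(-stats$precision, -stats$n_active, stats$size,
              stats$fragment), , drop = FALSE]
}

# per-molecule fragment sets plus an inverted index fragment -> molecules
.fragmentIndex <- function(x, config) {
  df <- moleculeData(x)
  labs <- df$label
  if (!all(labs %in% c("active", "inactive")))
    stop("mining requires every record labeled active or inactive")
  if (!any(labs == "active"))
    warning("no active molecules: nothing to mine")
  sets <- lapply(df$smiles, enumerateFragments, config = config)
  frags <- unique(unlist(sets, use.names = FALSE))
  byFrag <- new.env(parent = emptyenv())
  for (i in seq_along(sets))
    for (f in sets[[i]]) byFrag[[f]] <- c(byFrag[[f]], i)
  list(fragments = frags, byFrag = byFrag, active = labs == "active",
       ids = df$record_id, sets = sets)
}

.fragmentStats <- function(idx) {
  if (!length(idx$fragments))
    return(data.frame(fragment = character(0), n_active = integer(0),
                      n_inactive = integer(0), precision = numeric(0),
                      size = integer(0)))
  nAct <- vapply(idx$fragments, function(f)
    sum(idx$active[idx$byFrag[[f]]]), integer(1))
  nIna <- vapply(idx$fragments, function(f)
    sum(!idx$active[idx$byFrag[[f]]]), integer(1))
  data.frame(fragment = idx$fragments, n_active = nAct, n_inactive = nIna,
             precision = nAct / (nAct + nIna),
             size = unname(.countHeavyAtoms(idx$fragments)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Mine structural alerts from a labeled set
#'
#' Greedy covering: repeatedly pick the candidate fragment with the best
#' (precision, active support, smaller size, lexicographic text) key among
#' those meeting the support and precision floors, emit it as a rule, and
#' remove the active molecules it covers; support and precision are
#' re-evaluated on the remaining actives (inactive counts stay fixed).
#' Selection stops when no candidate qualifies. Emitted rules carry
#' `n_tot`/`n_true`/`ppv` recomputed on the full input set by substructure
#' matching.
#'
#' @param x a labeled [MoleculeSet-class].
#' @param config a [miningConfig()].
#' @return an [AlertLibrary-class] with endpoint `"mined"`; empty when no
#'   fragment qualifies.
#' @export
extractAlerts <- function(x, config = miningConfig()) {
  idx <- .fragmentIndex(x, config)
  emptyLib <- new("AlertLibrary",
                  rules = data.frame(alert_id = integer(0),
                                     smiles = character(0),
                                     endpoint = character(0),
                                     n_tot = integer(0), n_true = integer(0),
                                     ppv = numeric(0),
                                     chemical_class = character(0)),
                  endpoint = "mined")
  if (!length(idx$fragments)) return(emptyLib)
  remaining <- which(idx$active)
  nIna <- vapply(idx$fragments, function(f)
    sum(!idx$active[idx$byFrag[[f]]]), integer(1))
  size <- unname(.countHeavyAtoms(idx$fragments))
  chosen <- character(0)
  while (length(remaining) && length(chosen) < config$maxRules) {
    nAct <- vapply(idx$fragments, function(f)
      length(intersect(idx$byFrag[[f]], remaining)), integer(1))
    prec <- nAct / (nAct + nIna)
    ok <- nAct >= config$minSupportActive & prec >= config$minPrecision &
      !(idx$fragments %in% chosen)
    if (!any(ok)) break
    cand <- which(ok)
    ord <- cand[order(-prec[cand], -nAct[cand], size[cand],
                      idx$fragments[cand])]
    best <- ord[1]
    chosen <- c(chosen, idx$fragments[best])
    remaining <- setdiff(remaining, idx$byFrag[[idx$fragments[best]]])
  }
  if (!length(chosen)) return(emptyLib)
  lib <- new("AlertLibrary",
             rules = data.frame(alert_id = seq_along(chosen),
                                smiles = chosen, endpoint = "mined",
                                n_tot = 0L, n_true = 0L, ppv = NA_real_,
                                chemical_class = NA_character_,
                                stringsAsFactors = FALSE),
             endpoint = "mined")
  m <- matchAlerts(x, lib)
  active <- idx$active
  rules <- alertRules(lib)
  rules$n_tot <- as.integer(colSums(m))
  rules$n_true <- as.integer(colSums(m & active))
  rules$ppv <- computePpv(rules$n_true, rules$n_tot)
  new("AlertLibrary", rules = rules, endpoint = "mined")
}

#' Write an alert library as CSV
#'
#' Output schema matches the packaged alert tables, so mined libraries can
#' be re-loaded and used anywhere a packaged library is accepted.
#'
#' @param library an [AlertLibrary-class].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeAlertLibrary <- function(library, file) {
  utils::write.csv(alertRules(library), file, row.names = FALSE)
  invisible(file)
}

#' Read an alert library from CSV
#'
#' @param file CSV with columns `alert_id`, `smiles`, `endpoint`,
#'   `n_tot`, `n_true`, `chemical_class` (and optionally `ppv`).
#' @param endpoint endpoint tag for the library; default taken from the
#'   file contents.
#' @return an [AlertLibrary-class].
#' @export
readAlertLibrary <- function(file, endpoint = NULL) {
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  tab$ppv <- computePpv(tab$n_true, tab$n_tot)
  if (is.null(endpoint))
    endpoint <- if (nrow(tab)) tab$endpoint[1] else "mined"
  bad <- !vapply(tab$smiles, .validPattern, logical(1))
  if (any(bad))
    stop("alert library integrity error: unparsable pattern(s): ",
         paste(tab$smiles[bad], collapse = ", "))
  new("AlertLibrary", rules = tab, endpoint = endpoint)
}

#' Planted-motif recovery under match-set equivalence
#'
#' A planted motif counts as recovered when some mined rule matches
#' exactly the same set of active molecules as the motif itself — text
#' equality is not required (a mined fragment containing the motif, or a
#' sub-fragment with identical coverage, recovers it).
#'
#' @param library a mined [AlertLibrary-class].
#' @param x the labeled [MoleculeSet-class] the rules were mined from.
#' @param motifs character vector of planted motif patterns.
#' @return named logical vector, one element per motif.
#' @export
motifRecovery <- function(library, x, motifs) {
  labs <- moleculeLabels(x)
  act <- which(labs == "active")
  motifLib <- new("AlertLibrary",
                  rules = data.frame(alert_id = seq_along(motifs),
                                     smiles = motifs, endpoint = "motif",
                                     n_tot = 0L, n_true = 0L,
                                     ppv = NA_real_,
                                     chemical_class = NA_character_,
                                     stringsAsFactors = FALSE),
                  endpoint = "mined")
  mm <- matchAlerts(x, motifLib)[act, , drop = FALSE]
  if (!length(library)) {
    return(stats::setNames(rep(FALSE, length(motifs)), motifs))
  }
  rm <- matchAlerts(x, library)[act, , drop = FALSE]
  out <- vapply(seq_along(motifs), function(i) {
    target <- mm[, i]
    any(vapply(seq_len(ncol(rm)), function(j)
      identical(unname(rm[, j]), unname(target)), logical(1)))
  }, logical(1))
  stats::setNames(out, motifs)
}
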