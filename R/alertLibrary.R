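# Packaged structural-alert libraries, substructure matching, and dataset
# profiling. The irritation library carries the 13 published respiratory
# irritation alerts, the sensitization library the 18 respiratory
# sensitization alerts; patterns are plain SMILES used as substructure
# queries (element and bond-order constraints, aromatic atoms aromatic, no
# added hydrogen-count constraints).

.probeSDF <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- suppressWarnings(ChemmineR::smiles2sdf(c(probe = "CCO")))
    cache
  }
})

.validPattern <- function(pattern) {
  ok <- tryCatch({
    ChemmineR::smartsSearchOB(.probeSDF(), pattern, uniqueMatches = TRUE)
    TRUE
  }, error = function(e) FALSE)
  isTRUE(ok)
}

#' Load a packaged structural-alert library
#'
#' Returns the published alert table for an endpoint: 13 rules for
#' respiratory irritation or 18 rules for respiratory sensitization, each
#' with its substructure pattern, occurrence counts on the source data
#' (`n_tot` in all molecules, `n_true` in actives), the PPV implied by
#' those counts, and a chemical-class annotation. Every pattern is
#' validated as a substructure query at load time.
#'
#' @param endpoint `"irritation"` or `"sensitization"`.
#' @return an [AlertLibrary-class].
#' @examples
#' alertLibrary("irritation")
#' @export
alertLibrary <- function(endpoint = c("irritation", "sensitization")) {
  endpoint <- match.arg(endpoint)
  path <- system.file("extdata",
                      paste0("alerts_", endpoint, ".csv"),
                      package = "respiscreen", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$ppv <- tab$n_true / tab$n_tot
  bad <- !vapply(tab$smiles, .validPattern, logical(1))
  if (any(bad))
    stop("alert library integrity error: unparsable pattern(s): ",
         paste(tab$smiles[bad], collapse = ", "))
  new("AlertLibrary", rules = tab, endpoint = endpoint)
}

#' Match structural alerts against molecules
#'
#' An alert matches a molecule when its pattern occurs as a subgraph
#' (substructure search via Open Babel SMARTS). A molecule matching one
#' alert several times still counts as a single match.
#'
#' @param x a [MoleculeSet-class], or a character vector of SMILES.
#' @param library an [AlertLibrary-class].
#' @return a logical matrix, one row per record and one column per
#'   `alert_id`. Molecules whose structure cannot be converted for
#'   searching get all-`FALSE` rows.
#' @examples
#' lib <- alertLibrary("irritation")
#' x <- MoleculeSet(data.frame(record_id = "aa", smiles = "CC(=O)OC(=O)C"))
#' which(matchAlerts(x, lib)[1, ])
#' @export
matchAlerts <- function(x, library) {
  if (is.character(x))
    x <- MoleculeSet(data.frame(record_id = names2ids(x), smiles = x))
  stopifnot(is(x, "MoleculeSet"), is(library, "AlertLibrary"))
  ids <- moleculeData(x)$record_id
  rules <- alertRules(library)
  out <- matrix(FALSE, nrow = length(ids), ncol = nrow(rules),
                dimnames = list(ids, as.character(rules$alert_id)))
  sdf <- .toSDFset(x)
  if (is.null(sdf) || !nrow(rules)) return(out)
  present <- ChemmineR::cid(sdf)
  for (j in seq_len(nrow(rules))) {
    hits <- tryCatch(
      ChemmineR::smartsSearchOB(sdf, rules$smiles[j], uniqueMatches = TRUE),
      error = function(e) stop("alert library integrity error: pattern '",
                               rules$smiles[j], "' failed: ",
                               conditionMessage(e)))
    out[match(present, ids), j] <- hits > 0
  }
  out
}

names2ids <- function(x) {
  if (!is.null(names(x)) && all(nzchar(names(x)))) names(x)
  else sprintf("rec%04d", seq_along(x))
}

#' Positive predictive value of an alert
#'
#' `ppv = n_true / n_tot`, the fraction of a pattern's occurrences that
#' fall in active molecules. Undefined (`NA`) when `n_tot` is zero — never
#' coerced to 0 or 1.
#'
#' @param nTrue occurrences in active molecules.
#' @param nTot total occurrences.
#' @return numeric vector of PPVs, `NA` where undefined.
#' @examples
#' computePpv(108, 117)  # 0.92 to 2 dp
#' @export
computePpv <- function(nTrue, nTot) {
  stopifnot(all(nTot >= nTrue, na.rm = TRUE), all(nTrue >= 0, na.rm = TRUE))
  ifelse(nTot > 0, nTrue / nTot, NA_real_)
}

#' Profile a labeled dataset against an alert library
#'
#' Recomputes each alert's occurrence counts on the supplied set (one
#' molecule counts at most once per alert) and the set-level confusion:
#' molecules matching at least one alert are flagged, `set_tp` of them are
#' active and `set_fp` inactive, giving
#' `set_ppv = set_tp / (set_tp + set_fp)`.
#'
#' @param x a [MoleculeSet-class]; every record must be labeled `active`
#'   or `inactive`.
#' @param library an [AlertLibrary-class].
#' @return an `AlertProfile` list: `per_alert` data.frame (alert_id,
#'   n_tot, n_true, ppv), `set_tp`, `set_fp`, `set_ppv`, and the logical
#'   `matched` matrix.
#' @export
profileDataset <- function(x, library) {
  stopifnot(is(x, "MoleculeSet"))
  labs <- moleculeLabels(x)
  if (length(labs) && any(labs == "unlabeled"))
    stop("profileDataset requires every record labeled active or inactive")
  m <- matchAlerts(x, library)
  active <- labs == "active"
  perAlert <- data.frame(
    alert_id = alertRules(library)$alert_id,
    n_tot = as.integer(colSums(m)),
    n_true = as.integer(colSums(m & active)),
    stringsAsFactors = FALSE)
  perAlert$ppv <- computePpv(perAlert$n_true, perAlert$n_tot)
  any <- rowSums(m) > 0
  tp <- sum(any & active)
  fp <- sum(any & !active)
  structure(list(per_alert = perAlert, set_tp = tp, set_fp = fp,
                 set_ppv = computePpv(tp, tp + fp), matched = m),
            class = "AlertProfile")
}

#' @export
print.AlertProfile <- function(x, ...) {
  cat("AlertProfile:", nrow(x$matched), "molecules,",
      nrow(x$per_alert), "alerts\n")
  cat("  flagged: tp =", x$set_tp, ", fp =", x$set_fp,
      ", set-level PPV =",
      if (is.na(x$set_ppv)) "undefined" else format(round(x$set_ppv, 3)),
      "\n")
  hit <- x$per_alert[x$per_alert$n_tot > 0, , drop = FALSE]
  if (nrow(hit)) {
    cat("  alerts with occurrences:\n")
    print(hit, row.names = FALSE)
  }
  invisible(x)
}
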