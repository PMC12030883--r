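# Integration of alert calls and consensus-model calls into a confidence
# score. Alert-based prediction has no "Inactive" state: a molecule with
# no alert is Inconclusive, since absence of an alert is absence of
# evidence, not evidence of absence.

.SCORE_TABLE <- data.frame(
  alert_call = c("Active", "Active", "Inconclusive", "Inconclusive",
                 "Active", "Inconclusive"),
  ml_call = c("Active", "Inconclusive", "Active", "Inconclusive",
              "Inactive", "Inactive"),
  confidence_score = c(2, 1, 1, 0, -1, NA),
  final_category = c("Likely-toxicant", "Possible-toxicant",
                     "Possible-toxicant", "Unresolved", "Conflict",
                     "Predicted-inactive"),
  stringsAsFactors = FALSE)

#' Combine an alert call and a model call into a confidence score
#'
#' Scoring scheme: both `Active` scores 2 (Likely-toxicant); one `Active`
#' and one `Inconclusive` scores 1 (Possible-toxicant); both
#' `Inconclusive` scores 0 (Unresolved); alerts `Active` against a model
#' `Inactive` call scores -1 (Conflict). The remaining combination — no
#' alert and a model `Inactive` call — has no published score and is
#' reported as `NA` / Predicted-inactive rather than overloading 0.
#'
#' @param alertCall `"Active"` or `"Inconclusive"` (vectorised).
#' @param mlCall `"Active"`, `"Inactive"`, or `"Inconclusive"`
#'   (vectorised).
#' @return data.frame with `confidence_score` and `final_category`.
#' @examples
#' integrateCalls("Active", "Active")        # 2
#' integrateCalls("Active", "Inactive")      # -1
#' @export
integrateCalls <- function(alertCall, mlCall) {
  stopifnot(all(alertCall %in% c("Active", "Inconclusive")),
            all(mlCall %in% c("Active", "Inactive", "Inconclusive")))
  n <- max(length(alertCall), length(mlCall))
  alertCall <- rep_len(alertCall, n)
  mlCall <- rep_len(mlCall, n)
  i <- match(paste(alertCall, mlCall),
             paste(.SCORE_TABLE$alert_call, .SCORE_TABLE$ml_call))
  out <- .SCORE_TABLE[i, c("confidence_score", "final_category"),
                      drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Screen a chemical list with alerts plus a consensus model
#'
#' For every record: substructure search against the alert library gives
#' the alert call (`Active` iff at least one alert matches), the consensus
#' model gives the model call (with out-of-domain and unfeaturizable
#' molecules `Inconclusive`), and the two are combined into the
#' confidence score. Set-algebra identities (score 2 = alert-Active AND
#' model-Active; score -1 = alert-Active AND model-Inactive; count
#' conservation over all scores) are asserted on every run.
#'
#' @param x a [MoleculeSet-class] of curated chemicals.
#' @param library an [AlertLibrary-class].
#' @param model a [ConsensusModel-class].
#' @return a `ScreeningReport` list: `results` data.frame (record_id,
#'   smiles, matched_alerts, alert_call, ml_call, y_mean, cons_std,
#'   confidence_score, final_category), `summary` with counts per score
#'   and category, and `alert_ranking` — per-alert occurrence counts among
#'   the score-2 chemicals.
#' @export
screenChemicals <- function(x, library, model) {
  stopifnot(is(x, "MoleculeSet"), is(library, "AlertLibrary"),
            is(model, "ConsensusModel"))
  df <- moleculeData(x)
  if (!nrow(df)) {
    return(structure(list(
      results = data.frame(), summary = list(
        n = 0L, by_score = integer(0), by_category = integer(0)),
      alert_ranking = data.frame()), class = "ScreeningReport"))
  }
  m <- matchAlerts(x, library)
  alertCall <- ifelse(rowSums(m) > 0, "Active", "Inconclusive")
  matched <- apply(m, 1, function(r)
    paste(colnames(m)[r], collapse = ";"))
  pred <- predictConsensus(model, x)
  sc <- integrateCalls(alertCall, pred$call)
  results <- data.frame(
    record_id = df$record_id, smiles = df$smiles,
    matched_alerts = unname(matched), alert_call = unname(alertCall),
    ml_call = pred$call, y_mean = pred$y_mean, cons_std = pred$cons_std,
    confidence_score = sc$confidence_score,
    final_category = sc$final_category,
    stringsAsFactors = FALSE)
  byScore <- c(`2` = sum(results$confidence_score %in% 2),
               `1` = sum(results$confidence_score %in% 1),
               `0` = sum(results$confidence_score %in% 0),
               `-1` = sum(results$confidence_score %in% -1),
               `NA` = sum(is.na(results$confidence_score)))
  stopifnot(sum(byScore) == nrow(results))
  score2 <- results$confidence_score %in% 2
  stopifnot(identical(which(score2),
                      unname(which(alertCall == "Active" &
                                     pred$call == "Active"))),
            identical(which(results$confidence_score %in% -1),
                      unname(which(alertCall == "Active" &
                                     pred$call == "Inactive"))))
  byCat <- table(results$final_category)
  occ <- colSums(m[score2, , drop = FALSE])
  ranking <- data.frame(alert_id = colnames(m),
                        n_score2 = as.integer(occ),
                        stringsAsFactors = FALSE)
  ranking <- ranking[order(-ranking$n_score2, ranking$alert_id), ,
                     drop = FALSE]
  rownames(ranking) <- NULL
  structure(list(results = results,
                 summary = list(n = nrow(results), by_score = byScore,
                                by_category = c(byCat)),
                 alert_ranking = ranking),
            class = "ScreeningReport")
}

#' @export
print.ScreeningReport <- function(x, ...) {
  cat("ScreeningReport:", x$summary$n, "chemicals\n")
  if (x$summary$n) {
    cat("  confidence scores:",
        paste(sprintf("%s=%d", names(x$summary$by_score),
                      x$summary$by_score), collapse = ", "), "\n")
    top <- utils::head(x$alert_ranking[x$alert_ranking$n_score2 > 0, ], 5)
    if (nrow(top)) {
      cat("  top alerts among score-2 chemicals:\n")
      print(top, row.names = FALSE)
    }
  }
  invisible(x)
}

#' Write screening outputs
#'
#' @param report a `ScreeningReport` from [screenChemicals()].
#' @param file CSV path for the per-chemical results.
#' @param summaryFile optional JSON path for the summary counts.
#' @return `file`, invisibly.
#' @export
writeScreeningReport <- function(report, file, summaryFile = NULL) {
  utils::write.csv(report$results, file, row.names = FALSE, na = "NA")
  if (!is.null(summaryFile))
    jsonlite::write_json(
      list(n = report$summary$n,
           by_score = as.list(report$summary$by_score),
           by_category = as.list(report$summary$by_category),
           alert_ranking = report$alert_ranking),
      summaryFile, auto_unbox = TRUE)
  invisible(file)
}
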