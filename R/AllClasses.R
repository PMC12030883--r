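#' @import methods
NULL

.LABELS <- c("active", "inactive", "unlabeled")
.ENDPOINTS <- c("irritation", "sensitization", "none")

.recordColumns <- c("record_id", "raw_input", "smiles", "dedup_key",
                    "label", "endpoint", "provenance")

#' MoleculeSet: a collection of chemical records
#'
#' Container for a set of chemicals, one row per record, holding the raw
#' input string, the Open Babel canonical SMILES (`smiles`), the InChIKey
#' deduplication key (`dedup_key`, filled during curation), an activity
#' label (`active`, `inactive` or `unlabeled`), the endpoint the label
#' refers to, and a free-text provenance tag.
#'
#' @slot records data.frame with columns `record_id`, `raw_input`,
#'   `smiles`, `dedup_key`, `label`, `endpoint`, `provenance`.
#' @seealso [parseStructures()], [curateStructures()],
#'   [deduplicateStructures()]
#' @export
setClass("MoleculeSet", representation(records = "data.frame"))

setValidity("MoleculeSet", function(object) {
  df <- object@records
  msg <- character(0)
  if (!all(.recordColumns %in% colnames(df)))
    msg <- c(msg, paste("records must have columns:",
                        paste(.recordColumns, collapse = ", ")))
  else {
    if (anyDuplicated(df$record_id))
      msg <- c(msg, "record_id values must be unique")
    if (!all(df$label %in% .LABELS))
      msg <- c(msg, "labels must be one of active/inactive/unlabeled")
    if (!all(df$endpoint %in% .ENDPOINTS))
      msg <- c(msg, "endpoint must be one of irritation/sensitization/none")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a MoleculeSet from a data.frame
#'
#' @param records data.frame with at least `record_id` and `smiles`
#'   columns; missing bookkeeping columns are filled with defaults
#'   (`label = "unlabeled"`, `endpoint = "none"`).
#' @return a [MoleculeSet-class] object.
#' @examples
#' MoleculeSet(data.frame(record_id = "m1", smiles = "CCO"))
#' @export
MoleculeSet <- function(records) {
  stopifnot(is.data.frame(records))
  df <- records
  n <- nrow(df)
  if (!"raw_input" %in% colnames(df)) df$raw_input <- df$smiles
  if (!"dedup_key" %in% colnames(df))
    df$dedup_key <- rep(NA_character_, n)
  if (!"label" %in% colnames(df)) df$label <- rep("unlabeled", n)
  if (!"endpoint" %in% colnames(df)) df$endpoint <- rep("none", n)
  if (!"provenance" %in% colnames(df))
    df$provenance <- rep(NA_character_, n)
  df$record_id <- as.character(df$record_id)
  df <- df[, .recordColumns, drop = FALSE]
  rownames(df) <- NULL
  new("MoleculeSet", records = df)
}

#' AlertLibrary: a set of structural-alert rules for one endpoint
#'
#' Each rule is a substructure pattern (plain SMILES interpreted as a
#' query), its endpoint, the occurrence counts on the source data
#' (`n_tot` over all molecules, `n_true` over active molecules), the
#' positive predictive value `ppv = n_true / n_tot`, and a chemical-class
#' annotation.
#'
#' @slot rules data.frame with columns `alert_id`, `smiles`, `endpoint`,
#'   `n_tot`, `n_true`, `ppv`, `chemical_class`.
#' @slot endpoint scalar character, `"irritation"`, `"sensitization"`, or
#'   `"mined"` for libraries produced by [extractAlerts()].
#' @seealso [alertLibrary()], [matchAlerts()], [profileDataset()]
#' @export
setClass("AlertLibrary",
         representation(rules = "data.frame", endpoint = "character"))

setValidity("AlertLibrary", function(object) {
  df <- object@rules
  need <- c("alert_id", "smiles", "endpoint", "n_tot", "n_true", "ppv",
            "chemical_class")
  msg <- character(0)
  if (!all(need %in% colnames(df)))
    msg <- c(msg, paste("rules must have columns:",
                        paste(need, collapse = ", ")))
  else if (nrow(df)) {
    if (any(df$n_true > df$n_tot | df$n_true < 0))
      msg <- c(msg, "need 0 <= n_true <= n_tot")
    ok <- df$n_tot > 0
    if (any(abs(df$ppv[ok] - df$n_true[ok] / df$n_tot[ok]) > 1e-9))
      msg <- c(msg, "ppv must equal n_true / n_tot")
    if (any(!nzchar(df$smiles)))
      msg <- c(msg, "every rule needs a non-empty pattern")
  }
  if (length(msg)) msg else TRUE
})

#' ConsensusModel: averaged base classifiers with a CONS-STD domain gate
#'
#' Holds the fitted base models (each a featurizer x learner pair), the
#' probability-averaging decision threshold, the calibrated CONS-STD
#' applicability-domain cutoff, and cross-validation bookkeeping from
#' training.
#'
#' @slot baseModels list of fitted base models.
#' @slot specs list of model specifications (see [modelSpec()]).
#' @slot adThreshold numeric CONS-STD cutoff; predictions with larger
#'   disagreement are out of domain and called `Inconclusive`.
#' @slot decisionThreshold numeric cutoff on the consensus mean for the
#'   `Active` call (default 0.5).
#' @slot cvInfo list with out-of-fold consensus statistics from training.
#' @seealso [trainConsensus()], [predictConsensus()]
#' @export
setClass("ConsensusModel",
         representation(baseModels = "list", specs = "list",
                        adThreshold = "numeric",
                        decisionThreshold = "numeric", cvInfo = "list"))

setMethod("show", "MoleculeSet", function(object) {
  df <- object@records
  cat("MoleculeSet with", nrow(df), "records\n")
  if (nrow(df)) {
    tab <- table(factor(df$label, levels = .LABELS))
    cat("  labels:", paste(sprintf("%s=%d", names(tab), tab),
                           collapse = ", "), "\n")
    cat("  first:", df$record_id[1], df$smiles[1], "\n")
  }
})

setMethod("show", "AlertLibrary", function(object) {
  cat("AlertLibrary (", object@endpoint, ") with ",
      nrow(object@rules), " rules\n", sep = "")
})

setMethod("show", "ConsensusModel", function(object) {
  cat("ConsensusModel with", length(object@baseModels), "base models\n")
  cat("  AD threshold (CONS-STD):",
      format(object@adThreshold, digits = 4), "\n")
  for (s in object@specs)
    cat("  -", s$featurizer, "x", s$learner, "\n")
})

setMethod("length", "MoleculeSet", function(x) nrow(x@records))
setMethod("length", "AlertLibrary", function(x) nrow(x@rules))

setMethod("[", "MoleculeSet", function(x, i, j, ..., drop = TRUE) {
  MoleculeSet(x@records[i, , drop = FALSE])
})

#' @describeIn MoleculeSet-class the underlying records data.frame.
#' @param x,object a `MoleculeSet`.
#' @export
moleculeData <- function(x) x@records

#' @describeIn MoleculeSet-class canonical SMILES, named by record id.
#' @export
moleculeSmiles <- function(x) {
  stats::setNames(x@records$smiles, x@records$record_id)
}

#' @describeIn MoleculeSet-class activity labels, named by record id.
#' @export
moleculeLabels <- function(x) {
  stats::setNames(x@records$label, x@records$record_id)
}

#' @describeIn AlertLibrary-class the rules table of an `AlertLibrary`.
#' @param x an `AlertLibrary`.
#' @export
alertRules <- function(x) x@rules

#' @describeIn ConsensusModel-class the calibrated CONS-STD cutoff.
#' @param x a `ConsensusModel`.
#' @export
adThreshold <- function(x) x@adThreshold

# MoleculeSet -> ChemmineR SDFset keyed by record_id. Structures that
# cannot be converted (e.g. single-atom molecules) are dropped; callers
# treat missing ids as conversion failures.
.toSDFset <- function(x) {
  smi <- moleculeSmiles(x)
  smi <- smi[!is.na(smi) & nzchar(smi)]
  if (!length(smi)) return(NULL)
  sdf <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(smi)),
                  error = function(e) NULL)
  if (is.null(sdf)) return(NULL)
  keep <- tryCatch(ChemmineR::validSDF(sdf), error = function(e)
    rep(FALSE, length(sdf)))
  sdf <- sdf[keep]
  if (!length(sdf)) NULL else sdf
}
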