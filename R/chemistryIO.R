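# Reading, curating and deduplicating chemical structure sets.
#
# Curation order matters: counterions are stripped before the metal check so
# that e.g. sodium acetate survives as acetic acid, while ferrocene-like
# single-component organometallics are still rejected.

.smilesElements <- function(smi) {
  if (is.na(smi) || !nzchar(smi)) return(character(0))
  brackets <- regmatches(smi, gregexpr("\\[[^]]*\\]", smi))[[1]]
  els <- character(0)
  for (b in brackets) {
    m <- regmatches(b, regexec("^\\[[0-9]*([A-Z][a-z]?|[a-z])", b))[[1]]
    if (length(m) == 2) {
      e <- m[2]
      if (e %in% c("b", "c", "n", "o", "p", "s", "se"))
        e <- paste0(toupper(substr(e, 1, 1)), substr(e, 2, 10))
      els <- c(els, e)
    }
  }
  rest <- gsub("\\[[^]]*\\]", "", smi)
  m <- regmatches(rest, gregexpr("Cl|Br|B|C|N|O|P|S|F|I|b|c|n|o|p|s",
                                 rest))[[1]]
  m[m %in% c("b", "c", "n", "o", "p", "s")] <-
    toupper(m[m %in% c("b", "c", "n", "o", "p", "s")])
  c(els, m)
}

.hasCarbon <- function(smi) "C" %in% .smilesElements(smi)

.netCharge <- function(smi) {
  brackets <- regmatches(smi, gregexpr("\\[[^]]*\\]", smi))[[1]]
  total <- 0L
  for (b in brackets) {
    m <- regmatches(b, regexec("([+-])([0-9]*)\\]$", b))[[1]]
    if (length(m) == 3) {
      mag <- if (nzchar(m[3])) as.integer(m[3]) else 1L
      total <- total + if (m[2] == "+") mag else -mag
    } else {
      reps <- regmatches(b, regexec("(\\++|-+)\\]$", b))[[1]]
      if (length(reps) == 2)
        total <- total +
          (if (substr(reps[2], 1, 1) == "+") 1L else -1L) * nchar(reps[2])
    }
  }
  total
}

# Neutralize simple ionized acid/base groups, moving the net charge toward
# zero only. Net-zero species (nitro groups, zwitterions) and permanently
# charged centers (quaternary N) are left untouched.
.neutralizeSmiles <- function(smi) {
  net <- .netCharge(smi)
  if (net == 0L) return(list(smiles = smi, changed = FALSE, residual = 0L))
  out <- smi
  if (net < 0L) {
    subs <- c("\\[O-\\]" = "O", "\\[S-\\]" = "S", "\\[N-\\]" = "N")
  } else {
    subs <- c("\\[NH4\\+\\]" = "N", "\\[NH3\\+\\]" = "N",
              "\\[NH2\\+\\]" = "N", "\\[NH\\+\\]" = "N",
              "\\[nH\\+\\]" = "[nH]", "\\[OH2\\+\\]" = "O",
              "\\[OH\\+\\]" = "O", "\\[SH\\+\\]" = "S")
  }
  todo <- abs(net)
  for (pat in names(subs)) {
    while (todo > 0L && grepl(pat, out)) {
      out <- sub(pat, subs[[pat]], out)
      todo <- todo - 1L
    }
    if (todo == 0L) break
  }
  can <- canonicalSmiles(out)
  if (is.na(can)) {
    # valence-violating rewrite: keep the ion as-is
    return(list(smiles = smi, changed = FALSE, residual = net))
  }
  list(smiles = can, changed = !identical(can, canonicalSmiles(smi)),
       residual = .netCharge(can))
}

#' Read chemical structures from SMILES, CSV, or SDF input
#'
#' Reads one record per input row or SDF entry. Entries whose SMILES cannot
#' be parsed are kept in the returned set with a missing canonical
#' structure and reported by [curateStructures()] as `n_unparsable`; they
#' are never silently dropped.
#'
#' @param file path to the input file.
#' @param format `"smiles"` (one SMILES per line, optional second column
#'   with an identifier), `"csv"`, or `"sdf"`; default guesses from the
#'   file extension.
#' @param smilesCol,idCol,labelCol CSV column names; `labelCol` values are
#'   mapped to `active`/`inactive` (1/0 and TRUE/FALSE also accepted).
#' @param endpoint endpoint tag stored on every record.
#' @param provenance free-text source tag stored on every record.
#' @return a [MoleculeSet-class]; records with unparsable structures carry
#'   `NA` canonical SMILES.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(id = "m1", smiles = "CCO", label = "inactive"),
#'           f, row.names = FALSE)
#' parseStructures(f)
#' @export
parseStructures <- function(file, format = c("auto", "smiles", "csv", "sdf"),
                            smilesCol = "smiles", idCol = "id",
                            labelCol = "label", endpoint = "none",
                            provenance = NA_character_) {
  format <- match.arg(format)
  if (!file.exists(file)) stop("input file not found: ", file)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(file))
    format <- switch(ext, smi = , smiles = , txt = "smiles",
                     csv = "csv", sdf = , mol = "sdf",
                     stop("cannot infer format from extension '", ext,
                          "'; pass format="))
  }
  if (format == "csv") {
    tab <- utils::read.csv(file, stringsAsFactors = FALSE)
    if (!smilesCol %in% colnames(tab))
      stop("CSV is missing the SMILES column '", smilesCol, "'")
    raw <- as.character(tab[[smilesCol]])
    ids <- if (idCol %in% colnames(tab)) as.character(tab[[idCol]]) else
      sprintf("rec%04d", seq_along(raw))
    labs <- if (labelCol %in% colnames(tab))
      .normalizeLabels(tab[[labelCol]]) else rep("unlabeled", length(raw))
  } else if (format == "smiles") {
    lines <- readLines(file, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    raw <- vapply(strsplit(lines, "[ \t]+"), `[`, character(1), 1)
    ids <- vapply(strsplit(lines, "[ \t]+"), function(p)
      if (length(p) > 1) p[2] else NA_character_, character(1))
    ids[is.na(ids)] <- sprintf("rec%04d", which(is.na(ids)))
    labs <- rep("unlabeled", length(raw))
  } else {
    sdf <- suppressWarnings(ChemmineR::read.SDFset(file))
    ok <- tryCatch(ChemmineR::validSDF(sdf),
                   error = function(e) rep(TRUE, length(sdf)))
    ids <- vapply(seq_along(sdf), function(i) {
      id <- tryCatch(ChemmineR::sdfid(sdf[i]), error = function(e) "")
      if (length(id) && nzchar(id)) id else sprintf("rec%04d", i)
    }, character(1))
    raw <- rep(NA_character_, length(sdf))
    if (any(ok)) {
      smi <- tryCatch(
        suppressWarnings(ChemmineR::sdf2smiles(sdf[which(ok)])),
        error = function(e) NULL)
      if (!is.null(smi)) raw[which(ok)] <- as.character(smi)
    }
    labs <- rep("unlabeled", length(sdf))
  }
  if (!length(raw)) {
    warning("empty input file: ", file)
    return(MoleculeSet(data.frame(record_id = character(0),
                                  smiles = character(0))))
  }
  ids <- make.unique(ids, sep = "_dup")
  can <- canonicalSmiles(raw)
  bad <- sum(is.na(can))
  if (bad) message(bad, " entr", if (bad == 1) "y" else "ies",
                   " could not be parsed as SMILES")
  MoleculeSet(data.frame(record_id = ids, raw_input = raw, smiles = can,
                         dedup_key = NA_character_, label = labs,
                         endpoint = endpoint, provenance = provenance,
                         stringsAsFactors = FALSE))
}

.normalizeLabels <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- ifelse(x %in% c("active", "positive", "1", "true", "yes"), "active",
         ifelse(x %in% c("inactive", "negative", "0", "false", "no"),
                "inactive", "unlabeled"))
  out[is.na(x) | !nzchar(x)] <- "unlabeled"
  out
}

#' Curate a parsed structure set
#'
#' Applies the standard QSAR-ready cleanup: counterions are removed so a
#' salt is reduced to its largest (unique) organic component; structures
#' that remain multi-component are rejected as mixtures; carbon-free
#' structures are rejected as inorganic; structures containing atoms
#' outside H, B, C, N, O, F, Si, P, S, Cl, Se, Br, I are rejected as
#' metallo-organics; and simple ionized acid/base groups are neutralized
#' (net-zero zwitterions and permanent cations are kept as-is and logged).
#' Rejection is a logged outcome, never an error.
#'
#' @param x a [MoleculeSet-class] from [parseStructures()].
#' @return a list with `molecules` (the curated [MoleculeSet-class], with
#'   `dedup_key` filled in), `report` (a `CurationReport` list with the
#'   rejection tallies), and `log` (data.frame with one row per rejected or
#'   modified record).
#' @examples
#' x <- MoleculeSet(data.frame(record_id = c("a", "b"),
#'                             smiles = c("CC(=O)[O-].[Na+]", "O=[Si]=O")))
#' curateStructures(x)$report
#' @export
curateStructures <- function(x) {
  stopifnot(is(x, "MoleculeSet"))
  df <- moleculeData(x)
  n <- nrow(df)
  keep <- logical(n)
  outSmiles <- rep(NA_character_, n)
  category <- rep("ok", n)
  note <- rep("", n)
  for (i in seq_len(n)) {
    smi <- df$smiles[i]
    if (is.na(smi) || !nzchar(smi)) {
      category[i] <- "unparsable"
      note[i] <- paste0("not a valid SMILES: ", df$raw_input[i])
      next
    }
    comps <- strsplit(smi, ".", fixed = TRUE)[[1]]
    organic <- unique(comps[vapply(comps, .hasCarbon, logical(1))])
    if (length(organic) == 0L) {
      category[i] <- "inorganic"
      note[i] <- "no carbon-containing component"
      next
    }
    if (length(organic) > 1L) {
      category[i] <- "mixture"
      note[i] <- "multiple distinct organic components after desalting"
      next
    }
    surv <- organic[[1]]
    els <- unique(.smilesElements(surv))
    metal <- setdiff(els, .ORGANIC_ELEMENTS)
    if (length(metal)) {
      category[i] <- "organometallic"
      note[i] <- paste("contains disallowed element(s):",
                       paste(metal, collapse = ","))
      next
    }
    if (length(comps) > 1L)
      note[i] <- "counterion(s) removed"
    neut <- .neutralizeSmiles(surv)
    if (neut$changed)
      note[i] <- paste0(note[i], if (nzchar(note[i])) "; ", "neutralized")
    if (neut$residual != 0L)
      note[i] <- paste0(note[i], if (nzchar(note[i])) "; ",
                        "residual formal charge ", neut$residual,
                        " kept as-is")
    else if (grepl("[+-]", neut$smiles))
      note[i] <- paste0(note[i], if (nzchar(note[i])) "; ",
                        "charge-separated (net-neutral) species ",
                        "kept as-is")
    keep[i] <- TRUE
    outSmiles[i] <- canonicalSmiles(neut$smiles)
  }
  out <- df[keep, , drop = FALSE]
  out$smiles <- outSmiles[keep]
  out$dedup_key <- inchikey(out$smiles)
  # an InChIKey failure would leave dedup blind; fall back to the
  # canonical SMILES itself, which satisfies the same identity contract
  miss <- is.na(out$dedup_key)
  out$dedup_key[miss] <- out$smiles[miss]
  report <- structure(list(
    n_input = n,
    n_rejected_mixture = sum(category == "mixture"),
    n_rejected_inorganic = sum(category == "inorganic"),
    n_rejected_organometallic = sum(category == "organometallic"),
    n_unparsable = sum(category == "unparsable"),
    n_duplicates_merged = 0L,
    n_output = sum(keep)), class = "CurationReport")
  log <- data.frame(record_id = df$record_id, category = category,
                    note = note, stringsAsFactors = FALSE)
  log <- log[log$category != "ok" | nzchar(log$note), , drop = FALSE]
  rownames(log) <- NULL
  list(molecules = MoleculeSet(out), report = report, log = log)
}

#' @export
print.CurationReport <- function(x, ...) {
  cat("CurationReport\n")
  for (f in names(x)) cat(sprintf("  %-26s %d\n", f, x[[f]]))
  invisible(x)
}

#' Merge duplicate structures, positive label wins
#'
#' Collapses records sharing a deduplication key to a single record. When
#' merged records disagree on the activity label the survivor is labeled
#' `active`: negative calls are typically based on weaker, indirect
#' evidence, so a positive call anywhere wins.
#'
#' @param x a curated [MoleculeSet-class].
#' @param report optionally, the `CurationReport` from [curateStructures()];
#'   if given, its `n_duplicates_merged`/`n_output` fields are updated.
#' @return a list with `molecules`, `n_merged`, and (if supplied) the
#'   updated `report`.
#' @examples
#' x <- MoleculeSet(data.frame(record_id = c("a", "b"),
#'                             smiles = c("CCO", "OCC"),
#'                             dedup_key = c("k1", "k1"),
#'                             label = c("active", "inactive")))
#' deduplicateStructures(x)$molecules
#' @export
deduplicateStructures <- function(x, report = NULL) {
  stopifnot(is(x, "MoleculeSet"))
  df <- moleculeData(x)
  key <- df$dedup_key
  key[is.na(key)] <- df$smiles[is.na(key)]
  groups <- split(seq_len(nrow(df)), key)
  survivors <- integer(0)
  labels <- character(0)
  for (g in groups) {
    g <- sort(g)
    survivors <- c(survivors, g[1])
    labs <- df$label[g]
    labels <- c(labels,
                if ("active" %in% labs) "active"
                else if ("inactive" %in% labs) "inactive"
                else "unlabeled")
  }
  ord <- order(survivors)
  out <- df[survivors[ord], , drop = FALSE]
  out$label <- labels[ord]
  nMerged <- nrow(df) - nrow(out)
  res <- list(molecules = MoleculeSet(out), n_merged = nMerged)
  if (!is.null(report)) {
    report$n_duplicates_merged <- nMerged
    report$n_output <- report$n_output - nMerged
    res$report <- report
  }
  res
}

#' Write a curated set, its report, and a rejection log
#'
#' @param x a [MoleculeSet-class].
#' @param file output CSV path (columns: record_id, smiles, dedup_key,
#'   label, endpoint).
#' @return `file`, invisibly.
#' @export
writeCuratedSet <- function(x, file) {
  df <- moleculeData(x)[, c("record_id", "smiles", "dedup_key", "label",
                            "endpoint")]
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' @rdname writeCuratedSet
#' @param report a `CurationReport`.
#' @export
writeCurationReport <- function(report, file) {
  jsonlite::write_json(unclass(report), file, auto_unbox = TRUE)
  invisible(file)
}

#' @rdname writeCuratedSet
#' @param log rejection-log data.frame from [curateStructures()].
#' @export
writeRejectionLog <- function(log, file) {
  writeLines(sprintf("%s\t%s\t%s", log$record_id, log$category, log$note),
             file)
  invisible(file)
}
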