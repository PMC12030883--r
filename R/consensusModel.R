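# Consensus classification: several base models (featurizer x learner
# pairs) are trained on the same molecules; the consensus output for a
# molecule is the mean of the base-model probabilities of the Active
# class, and the disagreement
#
#   CONS-STD_j = sqrt( (1/N) * sum_m (ybar_j - y_jm)^2 )
#
# gates the applicability domain: molecules whose CONS-STD exceeds the
# calibrated threshold are called Inconclusive.

.FEATURIZERS <- c("fp2", "maccs", "ap", "physchem")

#' Featurize molecules under a named scheme
#'
#' Deterministic numeric features per molecule: `"fp2"` (1024-bit Open
#' Babel path fingerprint), `"maccs"` (MACCS keys), `"ap"` (atom-pair
#' fingerprint folded to 512 bits), or `"physchem"` (MW, logP, TPSA,
#' H-bond donor/acceptor counts, molar refractivity, plus heavy-atom and
#' aromatic-atom counts). The same structure always maps to the same row
#' regardless of which other molecules are present.
#'
#' @param x a [MoleculeSet-class].
#' @param scheme featurization scheme name.
#' @return numeric matrix, one row per record (rownames = record ids) with
#'   a `scheme_id` attribute. Rows are `NA` for molecules the scheme could
#'   not featurize (downstream they become `Inconclusive`).
#' @examples
#' x <- MoleculeSet(data.frame(record_id = "e", smiles = "CCO"))
#' dim(featurize(x, "fp2"))
#' @export
featurize <- function(x, scheme = .FEATURIZERS) {
  scheme <- match.arg(scheme)
  stopifnot(is(x, "MoleculeSet"))
  ids <- moleculeData(x)$record_id
  sdf <- .toSDFset(x)
  mat <- NULL
  if (!is.null(sdf)) {
    mat <- tryCatch(switch(scheme,
      fp2 = as.matrix(ChemmineR::fingerprintOB(sdf, "FP2")),
      maccs = as.matrix(ChemmineR::fingerprintOB(sdf, "MACCS")),
      ap = as.matrix(ChemmineR::desc2fp(ChemmineR::sdf2ap(sdf),
                                        descnames = 512)),
      physchem = .physchemMatrix(x, sdf)),
      error = function(e) NULL)
  }
  ncolOut <- if (!is.null(mat)) ncol(mat) else
    switch(scheme, fp2 = 1024L, maccs = 166L, ap = 512L, physchem = 10L)
  out <- matrix(NA_real_, nrow = length(ids), ncol = ncolOut,
                dimnames = list(ids, if (!is.null(mat)) colnames(mat) else
                  paste0(scheme, seq_len(ncolOut))))
  if (!is.null(mat)) {
    hit <- match(rownames(mat), ids)
    out[hit[!is.na(hit)], ] <- mat[!is.na(hit), , drop = FALSE]
  }
  structure(out, scheme_id = scheme)
}

.physchemMatrix <- function(x, sdf) {
  p <- ChemmineR::propOB(sdf)
  num <- c("HBA1", "HBA2", "HBD", "logP", "MR", "MW", "nF", "TPSA")
  num <- intersect(num, colnames(p))
  m <- as.matrix(p[, num, drop = FALSE])
  storage.mode(m) <- "double"
  ids <- ChemmineR::cid(sdf)
  smi <- moleculeSmiles(x)[ids]
  heavy <- .countHeavyAtoms(smi)
  arom <- vapply(smi, function(s) {
    g <- .molGraph(s)
    if (is.null(g)) NA_integer_ else sum(g$aromatic)
  }, integer(1))
  m <- cbind(m, nHeavy = as.numeric(heavy), nAromatic = as.numeric(arom))
  rownames(m) <- ids
  m
}

#' Stratified train/test split
#'
#' Random split with `round(fractionTrain * N)` records in the training
#' partition, stratified by label so both partitions contain both classes
#' whenever possible. Single-class input is split unstratified with a
#' warning.
#'
#' @param x a [MoleculeSet-class] (N >= 5).
#' @param fractionTrain training fraction, default 0.8.
#' @param seed integer seed; identical seeds give identical plans.
#' @return a `SplitPlan` list with `train_ids`, `test_ids`,
#'   `fraction_train`, `seed`.
#' @examples
#' x <- MoleculeSet(data.frame(record_id = paste0("m", 1:10),
#'                             smiles = rep("CCO", 10),
#'                             label = rep(c("active", "inactive"), 5)))
#' lengths(splitTrainTest(x, seed = 1)[1:2])
#' @export
splitTrainTest <- function(x, fractionTrain = 0.8, seed = 1L) {
  stopifnot(is(x, "MoleculeSet"), fractionTrain > 0, fractionTrain < 1)
  df <- moleculeData(x)
  n <- nrow(df)
  if (n < 5) stop("need at least 5 records to split")
  target <- round(fractionTrain * n)
  labs <- df$label
  if (length(unique(labs)) < 2) {
    warning("single-class input: unstratified split")
    ids <- withr::with_seed(seed, sample(df$record_id))
    return(structure(list(train_ids = sort(ids[seq_len(target)]),
                          test_ids = sort(ids[-seq_len(target)]),
                          fraction_train = fractionTrain, seed = seed),
                     class = "SplitPlan"))
  }
  groups <- split(df$record_id, labs)
  sizes <- lengths(groups)
  raw <- sizes * target / n
  alloc <- floor(raw)
  rem <- target - sum(alloc)
  if (rem > 0) {
    ord <- order(raw - alloc, decreasing = TRUE)
    alloc[ord[seq_len(rem)]] <- alloc[ord[seq_len(rem)]] + 1
  }
  alloc <- pmin(alloc, sizes)
  train <- withr::with_seed(seed, unlist(lapply(seq_along(groups),
    function(i) sample(groups[[i]], alloc[i])), use.names = FALSE))
  structure(list(train_ids = sort(train),
                 test_ids = sort(setdiff(df$record_id, train)),
                 fraction_train = fractionTrain, seed = seed),
            class = "SplitPlan")
}

#' Specify one base model
#'
#' @param featurizer one of `"fp2"`, `"maccs"`, `"ap"`, `"physchem"`.
#' @param learner one of `"rf"` (random forest), `"xgb"` (gradient
#'   boosting), `"glmnet"` (ridge-penalised logistic regression).
#' @param params named list of learner overrides.
#' @return a `modelSpec` list.
#' @export
modelSpec <- function(featurizer = .FEATURIZERS,
                      learner = c("rf", "xgb", "glmnet"),
                      params = list()) {
  featurizer <- match.arg(featurizer)
  learner <- match.arg(learner)
  structure(list(featurizer = featurizer, learner = learner,
                 params = params,
                 id = paste(featurizer, learner, sep = "_")),
            class = "modelSpec")
}

#' Default consensus menu
#'
#' Five base models pairing complementary featurizers and learners,
#' mirroring the published consensus sizes (five members for irritation,
#' four for sensitization; pass any subset).
#'
#' @return list of [modelSpec()] objects.
#' @export
defaultModelSpecs <- function() {
  list(modelSpec("fp2", "rf"), modelSpec("maccs", "xgb"),
       modelSpec("ap", "rf"), modelSpec("physchem", "xgb"),
       modelSpec("physchem", "glmnet"))
}

.fitBase <- function(spec, X, y, seed) {
  ok <- stats::complete.cases(X)
  X <- X[ok, , drop = FALSE]
  y <- y[ok]
  if (length(unique(y)) < 2)
    stop("need both classes among featurizable training records")
  keep <- apply(is.finite(X), 2, all)
  X <- X[, keep, drop = FALSE]
  mu <- colMeans(X)
  fit <- withr::with_seed(seed, switch(spec$learner,
    rf = randomForest::randomForest(
      x = X, y = factor(y, levels = c("inactive", "active")),
      ntree = spec$params$ntree %||% 200L),
    xgb = xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    max_depth = spec$params$max_depth %||% 4L,
                    eta = spec$params$eta %||% 0.3, nthread = 1L),
      data = xgboost::xgb.DMatrix(X, label = as.numeric(y == "active")),
      nrounds = spec$params$nrounds %||% 50L, verbose = 0),
    glmnet = glmnet::glmnet(
      X, factor(y, levels = c("inactive", "active")),
      family = "binomial", alpha = 0,
      lambda = spec$params$lambda %||% 0.05)))
  structure(list(spec = spec, fit = fit, keep = keep, mu = mu),
            class = "baseModel")
}

.predictBase <- function(model, X) {
  X <- X[, model$keep, drop = FALSE]
  bad <- !stats::complete.cases(X)
  # mean-impute stray missing values; fully-missing rows stay NA
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j]) & !bad
    if (any(nas)) X[nas, j] <- model$mu[j]
  }
  out <- rep(NA_real_, nrow(X))
  ok <- which(!bad)
  if (length(ok)) {
    Xok <- X[ok, , drop = FALSE]
    out[ok] <- switch(model$spec$learner,
      rf = stats::predict(model$fit, Xok, type = "prob")[, "active"],
      xgb = stats::predict(model$fit, xgboost::xgb.DMatrix(Xok)),
      glmnet = as.numeric(stats::predict(model$fit, Xok,
                                         type = "response")))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.makeFolds <- function(labels, k, seed) {
  n <- length(labels)
  fold <- integer(n)
  withr::with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Stratified cross-validation of one base model
#'
#' @param spec a [modelSpec()].
#' @param x a labeled [MoleculeSet-class].
#' @param k number of folds (default 5).
#' @param seed integer seed controlling fold assignment and learner
#'   randomness.
#' @return list with `predictions` (data.frame record_id, fold, y_prob,
#'   label) and `metrics` (a `MetricsReport`); every molecule gets exactly
#'   one out-of-fold prediction.
#' @export
crossValidate <- function(spec, x, k = 5L, seed = 1L) {
  df <- moleculeData(x)
  stopifnot(all(df$label %in% c("active", "inactive")))
  if (k < 2) stop("k must be >= 2")
  if (k > nrow(df)) stop("k exceeds the number of records")
  feats <- featurize(x, spec$featurizer)
  oof <- .cvProbs(spec, feats, df$label, k, seed)
  preds <- data.frame(record_id = df$record_id, fold = oof$fold,
                      y_prob = oof$prob, label = df$label,
                      stringsAsFactors = FALSE)
  list(predictions = preds,
       metrics = .metricsFromScores(oof$prob, df$label))
}

.cvProbs <- function(spec, feats, labels, k, seed) {
  fold <- .makeFolds(labels, k, seed)
  prob <- rep(NA_real_, length(labels))
  usable <- stats::complete.cases(feats)
  for (f in seq_len(k)) {
    tr <- which(fold != f & usable)
    te <- which(fold == f)
    if (length(unique(labels[tr])) < 2) next
    m <- .fitBase(spec, feats[tr, , drop = FALSE], labels[tr],
                  seed = seed + f)
    prob[te] <- .predictBase(m, feats[te, , drop = FALSE])
  }
  list(fold = fold, prob = prob)
}

#' Train a consensus model
#'
#' Fits every base model on the full training set, and calibrates the
#' applicability-domain cutoff as the `adQuantile` quantile of the
#' out-of-fold CONS-STD values from k-fold cross-validation, so that about
#' `1 - adQuantile` of training-like molecules fall outside the domain.
#' Optional greedy forward selection on cross-validated AUC can prune the
#' menu; by default all members are kept.
#'
#' @param x a labeled [MoleculeSet-class] (both classes present).
#' @param specs list of [modelSpec()]s (at least 2).
#' @param k cross-validation folds for calibration.
#' @param seed integer seed for folds and learners.
#' @param adQuantile quantile of cross-validated CONS-STD used as the
#'   domain cutoff (default 0.95).
#' @param decisionThreshold consensus-mean cutoff for the Active call.
#' @param select if `TRUE`, greedy forward selection on CV AUC decides
#'   which members enter the consensus.
#' @return a [ConsensusModel-class].
#' @export
trainConsensus <- function(x, specs = defaultModelSpecs(), k = 5L,
                           seed = 1L, adQuantile = 0.95,
                           decisionThreshold = 0.5, select = FALSE) {
  stopifnot(is(x, "MoleculeSet"), length(specs) >= 2)
  df <- moleculeData(x)
  labs <- df$label
  if (!all(labs %in% c("active", "inactive")) ||
      length(unique(labs)) < 2)
    stop("training requires both active and inactive labeled records")
  schemes <- unique(vapply(specs, function(s) s$featurizer, character(1)))
  featList <- lapply(stats::setNames(schemes, schemes),
                     function(s) featurize(x, s))
  oof <- lapply(specs, function(s)
    .cvProbs(s, featList[[s$featurizer]], labs, k, seed)$prob)
  names(oof) <- vapply(specs, `[[`, character(1), "id")
  cvAuc <- vapply(oof, function(p) computeAuc(p, labs), numeric(1))
  keep <- seq_along(specs)
  if (select) {
    keep <- .greedySelect(oof, labs)
    specs <- specs[keep]
    oof <- oof[keep]
  }
  P <- do.call(cbind, oof)
  ymean <- rowMeans(P, na.rm = TRUE)
  cstd <- consStd(P)
  adCut <- stats::quantile(cstd, adQuantile, na.rm = TRUE, names = FALSE)
  fits <- lapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    feats <- featList[[s$featurizer]]
    usable <- stats::complete.cases(feats)
    if (!all(usable))
      warning(sum(!usable), " record(s) dropped from training: ",
              "featurization failed")
    .fitBase(s, feats[usable, , drop = FALSE], labs[usable],
             seed = seed + 100L + i)
  })
  new("ConsensusModel", baseModels = fits, specs = specs,
      adThreshold = adCut, decisionThreshold = decisionThreshold,
      cvInfo = list(
        oof = data.frame(record_id = df$record_id, label = labs, P,
                         y_mean = ymean, cons_std = cstd,
                         check.names = FALSE),
        auc = cvAuc, seed = seed, k = k, adQuantile = adQuantile,
        consensus_metrics = .metricsFromScores(ymean, labs,
                                               decisionThreshold)))
}

.greedySelect <- function(oof, labs) {
  chosen <- integer(0)
  pool <- seq_along(oof)
  bestAuc <- -Inf
  repeat {
    aucs <- vapply(pool, function(i) {
      P <- do.call(cbind, oof[c(chosen, i)])
      computeAuc(rowMeans(P, na.rm = TRUE), labs)
    }, numeric(1))
    if (!length(aucs) || max(aucs, na.rm = TRUE) <= bestAuc) break
    pick <- pool[which.max(aucs)]
    bestAuc <- max(aucs, na.rm = TRUE)
    chosen <- c(chosen, pick)
    pool <- setdiff(pool, pick)
  }
  if (length(chosen) < 2) chosen <- seq_len(min(2, length(oof)))
  sort(chosen)
}

#' Consensus disagreement (CONS-STD)
#'
#' Row-wise standard deviation of the base-model outputs with the 1/N
#' normalisation: `sqrt(mean((y_mean - y_m)^2))`. Zero exactly when all
#' models agree.
#'
#' @param P numeric matrix of per-model probabilities, one column per
#'   model.
#' @return numeric vector, one value per row.
#' @examples
#' consStd(matrix(c(0, 1), nrow = 1))  # 0.5
#' @export
consStd <- function(P) {
  P <- as.matrix(P)
  m <- rowMeans(P, na.rm = TRUE)
  sqrt(rowMeans((P - m)^2, na.rm = TRUE))
}

#' Predict with a consensus model
#'
#' @param model a [ConsensusModel-class].
#' @param x a [MoleculeSet-class].
#' @return data.frame with one row per record: per-model probabilities,
#'   `y_mean`, `cons_std`, `in_domain` (`cons_std <= adThreshold(model)`),
#'   and `call` — `Inconclusive` when out of domain or unfeaturizable,
#'   otherwise `Active`/`Inactive` by the decision threshold on `y_mean`.
#' @export
predictConsensus <- function(model, x) {
  stopifnot(is(model, "ConsensusModel"), is(x, "MoleculeSet"))
  df <- moleculeData(x)
  schemes <- unique(vapply(model@specs, `[[`, character(1), "featurizer"))
  featList <- lapply(stats::setNames(schemes, schemes),
                     function(s) featurize(x, s))
  P <- vapply(model@baseModels, function(m)
    .predictBase(m, featList[[m$spec$featurizer]]),
    numeric(nrow(df)))
  P <- matrix(P, nrow = nrow(df),
              dimnames = list(df$record_id,
                              vapply(model@specs, `[[`, character(1),
                                     "id")))
  ymean <- rowMeans(P, na.rm = TRUE)
  cstd <- consStd(P)
  failed <- apply(P, 1, function(r) all(is.na(r)))
  inDomain <- !failed & cstd <= model@adThreshold
  call <- ifelse(!inDomain, "Inconclusive",
                 ifelse(ymean >= model@decisionThreshold, "Active",
                        "Inactive"))
  out <- data.frame(record_id = df$record_id, P, y_mean = ymean,
                    cons_std = cstd, in_domain = inDomain, call = call,
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  out
}

#' Classification metrics from a confusion matrix
#'
#' `acc = (tp + tn) / (tp + tn + fn + fp)`, `sen = tp / (tp + fn)`,
#' `spe = tn / (tn + fp)`. Ratios with a zero denominator are `NA`
#' (undefined), never coerced.
#'
#' @param tp,fp,tn,fn confusion-matrix counts.
#' @return a `MetricsReport` list with the counts and `acc`, `sen`, `spe`.
#' @examples
#' computeMetrics(8, 2, 6, 4)
#' @export
computeMetrics <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0, tp + fp + tn + fn > 0)
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    acc = (tp + tn) / (tp + tn + fn + fp),
    sen = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    spe = if (tn + fp > 0) tn / (tn + fp) else NA_real_),
    class = "MetricsReport")
}

#' @export
print.MetricsReport <- function(x, ...) {
  cat(sprintf(
    "MetricsReport: tp=%d fp=%d tn=%d fn=%d | acc=%.3f sen=%s spe=%s",
    x$tp, x$fp, x$tn, x$fn, x$acc,
    ifelse(is.na(x$sen), "NA", sprintf("%.3f", x$sen)),
    ifelse(is.na(x$spe), "NA", sprintf("%.3f", x$spe))))
  if (!is.null(x$auc)) cat(sprintf(" auc=%.3f", x$auc))
  cat("\n")
  invisible(x)
}

.metricsFromScores <- function(scores, labels, threshold = 0.5) {
  ok <- !is.na(scores)
  pred <- scores[ok] >= threshold
  act <- labels[ok] == "active"
  m <- computeMetrics(tp = sum(pred & act), fp = sum(pred & !act),
                      tn = sum(!pred & !act), fn = sum(!pred & act))
  m$auc <- computeAuc(scores[ok], labels[ok])
  m
}

#' Rank-based AUC
#'
#' Area under the ROC curve computed from ranks (Wilcoxon statistic), with
#' ties contributing 1/2: the probability that a random active scores
#' above a random inactive.
#'
#' @param scores numeric scores, higher meaning more active.
#' @param labels `"active"`/`"inactive"` labels (or a logical vector with
#'   `TRUE` = active).
#' @return AUC in \[0, 1\]; `NA` with a warning if only one class is
#'   present.
#' @examples
#' computeAuc(c(0.9, 0.4, 0.6, 0.1),
#'            c("active", "active", "inactive", "inactive"))  # 0.75
#' @export
computeAuc <- function(scores, labels) {
  if (is.logical(labels)) labels <- ifelse(labels, "active", "inactive")
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  act <- labels == "active"
  nA <- sum(act); nI <- sum(!act)
  if (nA == 0 || nI == 0) {
    warning("AUC undefined: only one class present")
    return(NA_real_)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[act]) - nA * (nA + 1) / 2) / (nA * nI)
}

#' Save / load a consensus model
#'
#' The artifact stores base-model parameters, featurization scheme ids,
#' the AD threshold and training metrics; a round trip reproduces
#' predictions exactly.
#'
#' @param model a [ConsensusModel-class].
#' @param file path to the model artifact.
#' @return `file` (save) or the restored [ConsensusModel-class] (read).
#' @export
saveConsensusModel <- function(model, file) {
  saveRDS(list(format = "respiscreen-consensus-1", model = model), file)
  invisible(file)
}

#' @rdname saveConsensusModel
#' @export
readConsensusModel <- function(file) {
  obj <- readRDS(file)
  if (!identical(obj$format, "respiscreen-consensus-1"))
    stop("not a respiscreen consensus model artifact")
  obj$model
}
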