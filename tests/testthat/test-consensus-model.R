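test_that("featurization is deterministic and complete", {
  x <- MoleculeSet(data.frame(
    record_id = c("e1", "e2", "hex", "phen", "anh"),
    smiles = c("CCO", "CCO", "CCCCCC", "c1ccccc1O", "CC(=O)OC(=O)C")))
  for (scheme in c("fp2", "maccs", "physchem")) {
    f <- featurize(x, scheme)
    expect_equal(nrow(f), 5)
    expect_equal(attr(f, "scheme_id"), scheme)
    # identical canonical structures give identical rows
    expect_equal(unname(f["e1", ]), unname(f["e2", ]))
    # re-run equals itself
    expect_equal(featurize(x, scheme), f)
    expect_false(anyNA(f))
  }
  p <- featurize(x, "physchem")
  expect_true(all(is.finite(p)))
  expect_equal(unname(p["hex", "nHeavy"]), 6)
  expect_error(featurize(x, "quantum"))
})

test_that("train/test splits are sized, stratified, and reproducible", {
  x <- generateFeatureSeparableSet(100, 1, seed = 4)
  p <- splitTrainTest(x, seed = 1)
  expect_length(p$train_ids, 80)
  expect_length(p$test_ids, 20)
  expect_length(intersect(p$train_ids, p$test_ids), 0)
  labs <- moleculeLabels(x)
  expect_setequal(unique(labs[p$test_ids]), c("active", "inactive"))
  expect_identical(splitTrainTest(x, seed = 1), p)
  expect_false(identical(splitTrainTest(x, seed = 2)$train_ids,
                         p$train_ids))
  # N = 9 rounds to 7/2
  small <- x[c(1:5, 60:63)]  # 5 actives, 4 inactives
  p9 <- splitTrainTest(small, seed = 3)
  expect_length(p9$train_ids, 7)
  expect_length(p9$test_ids, 2)
  # single-class input still splits, with a warning
  onecls <- MoleculeSet(transform(moleculeData(x[1:10]),
                                  label = "active"))
  expect_warning(p1 <- splitTrainTest(onecls, seed = 1), "single-class")
  expect_length(p1$train_ids, 8)
  expect_error(splitTrainTest(x[1:4]), "at least 5")
})

test_that("cross-validation partitions records exactly once", {
  x <- generateFeatureSeparableSet(30, 1, seed = 8)
  cv <- crossValidate(modelSpec("fp2", "rf"), x, k = 5, seed = 2)
  expect_equal(sort(table(cv$predictions$fold)), sort(rep(6L, 5)),
               ignore_attr = TRUE)
  expect_equal(nrow(cv$predictions), 30)
  expect_false(anyNA(cv$predictions$y_prob))
  cv2 <- crossValidate(modelSpec("fp2", "rf"), x, k = 5, seed = 2)
  expect_identical(cv$predictions, cv2$predictions)
  expect_gt(cv$metrics$acc, 0.9)  # separable at separation 1
  expect_error(crossValidate(modelSpec("fp2", "rf"), x, k = 40), "exceeds")
})

test_that("CONS-STD follows its defining formula", {
  expect_equal(consStd(matrix(c(0.9, 0.9, 0.9), 1)), 0)
  expect_equal(consStd(matrix(c(0, 1), 1)), 0.5)
  P <- withr::with_seed(5, matrix(runif(60), 20, 3))
  expect_equal(consStd(P), consStd(P[, c(3, 1, 2)]))  # permutation
  expect_equal(consStd(P),
               sqrt(rowMeans((P - rowMeans(P))^2)))
  P2 <- withr::with_seed(6, matrix(runif(40), 20, 2))
  expect_true(all(consStd(P2) <= 0.5))  # N = 2 bound
  expect_true(all(consStd(P) >= 0))
})

test_that("a consensus of identical models is the identity", {
  x <- generateFeatureSeparableSet(40, 1, seed = 12)
  feats <- featurize(x, "fp2")
  base <- respiscreen:::.fitBase(modelSpec("fp2", "rf"), feats,
                                 moleculeData(x)$label, seed = 3)
  dup <- new("ConsensusModel",
             baseModels = list(base, base),
             specs = list(modelSpec("fp2", "rf"), modelSpec("fp2", "rf")),
             adThreshold = 0.1, decisionThreshold = 0.5, cvInfo = list())
  pred <- predictConsensus(dup, x)
  expect_equal(pred$y_mean, pred[[2]])
  expect_equal(pred$cons_std, rep(0, 40))
  expect_true(all(pred$in_domain))
  # gating overrides the mean when disagreement is too large
  tight <- new("ConsensusModel", baseModels = list(base, base),
               specs = dup@specs, adThreshold = -1,
               decisionThreshold = 0.5, cvInfo = list())
  expect_true(all(predictConsensus(tight, x)$call == "Inconclusive"))
})

test_that("training, prediction and serialization round-trip", {
  x <- generateFeatureSeparableSet(60, 1, seed = 21)
  mod <- trainConsensus(
    x, specs = list(modelSpec("fp2", "rf"), modelSpec("physchem", "xgb"),
                    modelSpec("maccs", "glmnet")),
    seed = 7)
  expect_s4_class(mod, "ConsensusModel")
  expect_gte(adThreshold(mod), 0)
  pred <- predictConsensus(mod, x)
  expect_equal(nrow(pred), 60)
  expect_true(all(pred$y_mean >= 0 & pred$y_mean <= 1))
  expect_true(all(pred$call %in% c("Active", "Inactive", "Inconclusive")))
  f <- tempfile(fileext = ".rds")
  saveConsensusModel(mod, f)
  back <- readConsensusModel(f)
  expect_equal(predictConsensus(back, x), pred)
  # degenerate labels refuse to train
  bad <- MoleculeSet(transform(moleculeData(x), label = "active"))
  expect_error(trainConsensus(bad, seed = 1), "both")
})

test_that("metrics match hand arithmetic and stay ordered", {
  m <- computeMetrics(10, 0, 10, 0)
  expect_equal(c(m$acc, m$sen, m$spe), c(1, 1, 1))
  m2 <- computeMetrics(8, 2, 6, 4)
  expect_equal(m2$acc, 0.7)
  expect_equal(m2$sen, 2 / 3)
  expect_equal(m2$spe, 0.75)
  m3 <- computeMetrics(0, 0, 5, 5)
  expect_equal(c(m3$acc, m3$sen, m3$spe), c(0.5, 0, 1))
  expect_true(is.na(computeMetrics(0, 3, 7, 0)$sen))
  # acc always lies between sen and spe when both are defined
  for (i in 1:20) {
    cnt <- withr::with_seed(i, rpois(4, 5) + c(1, 0, 1, 0))
    mm <- computeMetrics(cnt[1], cnt[2], cnt[3], cnt[4])
    expect_gte(mm$acc, min(mm$sen, mm$spe) - 1e-12)
    expect_lte(mm$acc, max(mm$sen, mm$spe) + 1e-12)
  }
})

test_that("rank AUC equals the pairwise probability and matches pROC", {
  expect_equal(computeAuc(c(0.9, 0.8, 0.2, 0.1),
                          c("active", "active", "inactive", "inactive")),
               1.0)
  expect_equal(computeAuc(rep(0.5, 10), rep(c("active", "inactive"), 5)),
               0.5)
  expect_equal(computeAuc(c(0.9, 0.4, 0.6, 0.1),
                          c("active", "active", "inactive", "inactive")),
               0.75)
  expect_warning(a <- computeAuc(1:3, rep("active", 3)), "one class")
  expect_true(is.na(a))
  s <- withr::with_seed(3, runif(50))
  l <- withr::with_seed(4, sample(c("active", "inactive"), 50, TRUE))
  ref <- as.numeric(suppressMessages(
    pROC::auc(pROC::roc(l, s, levels = c("inactive", "active"),
                        direction = "<"))))
  expect_equal(computeAuc(s, l), ref)
})

test_that("consensus recovers planted activity with high sen/spe", {
  # actives are defined by planted alert substructures; the consensus
  # should separate them from motif-free inactives at n = 400
  for (seed in 1:10) {
    d <- generateDataset(generatorConfig(
      nActive = 200, nInactive = 200, motifPool = benchmarkMotifs(),
      motifsPerDataset = 3, seed = seed))
    plan <- splitTrainTest(d$molecules, seed = seed)
    ids <- moleculeData(d$molecules)$record_id
    tr <- d$molecules[match(plan$train_ids, ids)]
    te <- d$molecules[match(plan$test_ids, ids)]
    mod <- trainConsensus(tr, seed = seed)
    pred <- predictConsensus(mod, te)
    ok <- pred$call != "Inconclusive"
    labs <- moleculeLabels(te)[ok]
    m <- computeMetrics(
      tp = sum(pred$call[ok] == "Active" & labs == "active"),
      fp = sum(pred$call[ok] == "Active" & labs == "inactive"),
      tn = sum(pred$call[ok] == "Inactive" & labs == "inactive"),
      fn = sum(pred$call[ok] == "Inactive" & labs == "active"))
    expect_gt(m$sen, 0.8)
    expect_gt(m$spe, 0.8)
  }
})
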