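test_that("packaged libraries load with verbatim patterns and counts", {
  irr <- alertLibrary("irritation")
  sen <- alertLibrary("sensitization")
  expect_s4_class(irr, "AlertLibrary")
  expect_equal(length(irr), 13)
  expect_equal(length(sen), 18)
  r1 <- alertRules(irr)[1, ]
  expect_equal(r1$smiles, "C(=O)OC(=O)")
  expect_equal(c(r1$n_tot, r1$n_true), c(13, 12))
  s1 <- alertRules(sen)[1, ]
  expect_equal(s1$smiles, "NCCO")
  expect_equal(c(s1$n_tot, s1$n_true), c(36, 33))
  # packaged ppv always reproduces the implied ratio exactly
  for (lib in list(irr, sen)) {
    tab <- alertRules(lib)
    expect_equal(tab$ppv, tab$n_true / tab$n_tot)
  }
  expect_error(alertLibrary("mutagenicity"))
})

test_that("substructure matching follows subgraph semantics", {
  irr <- alertLibrary("irritation")
  sen <- alertLibrary("sensitization")
  x <- MoleculeSet(data.frame(
    record_id = c("anhydride", "ethanol", "ethanolamine", "nitro"),
    smiles = c("CC(=O)OC(=O)C", "CCO", "NCCO", "CCC[N+](=O)[O-]")))
  m <- matchAlerts(x, irr)
  expect_true(m["anhydride", "1"])
  expect_false(any(m["ethanol", ]))          # no irritation alert at all
  expect_true(m["nitro", "9"])               # nitroparaffin
  m2 <- matchAlerts(x, sen)
  expect_true(m2["ethanolamine", "1"])       # pattern equals molecule
  # monotonicity: a match survives embedding into a larger molecule
  bigger <- MoleculeSet(data.frame(
    record_id = "grown", smiles = "CCCCC(NCCO)CC1CCCCC1"))
  expect_true(matchAlerts(bigger, sen)[1, "1"])
})

test_that("computePpv matches the printed set-level values", {
  expect_equal(round(computePpv(108, 117), 2), 0.92)
  expect_equal(round(computePpv(167, 178), 2), 0.94)
  expect_true(is.na(computePpv(0, 0)))
  expect_equal(computePpv(c(1, 0, 3), c(2, 0, 4)), c(0.5, NA, 0.75))
  expect_error(computePpv(5, 4))
})

test_that("dataset profiling recomputes counts at molecule level", {
  irr <- alertLibrary("irritation")
  empty <- MoleculeSet(data.frame(record_id = character(0),
                                  smiles = character(0)))
  p0 <- profileDataset(empty, irr)
  expect_equal(sum(p0$per_alert$n_tot), 0)
  expect_true(is.na(p0$set_ppv))

  x <- MoleculeSet(data.frame(
    record_id = c("a1", "a2", "i1"),
    smiles = c("CC(=O)OC(=O)C", "CCC(=O)OC(=O)CC", "CCCCCC"),
    label = c("active", "active", "inactive")))
  p <- profileDataset(x, irr)
  expect_equal(p$per_alert$n_tot[p$per_alert$alert_id == 1], 2)
  expect_equal(p$per_alert$n_true[p$per_alert$alert_id == 1], 2)
  expect_equal(p$set_ppv, 1.0)

  # a molecule with two anhydride groups still counts once
  twice <- MoleculeSet(data.frame(
    record_id = "dd", smiles = "CC(=O)OC(=O)CCCC(=O)OC(=O)C",
    label = "active"))
  pt <- profileDataset(twice, irr)
  expect_equal(pt$per_alert$n_tot[pt$per_alert$alert_id == 1], 1)

  unl <- MoleculeSet(data.frame(record_id = "u", smiles = "CCO"))
  expect_error(profileDataset(unl, irr), "labeled")
})

test_that("profiling is invariant to record order and rule duplication", {
  x <- MoleculeSet(data.frame(
    record_id = paste0("m", 1:4),
    smiles = c("CC(=O)OC(=O)C", "CCCCCC", "NCCO", "CCC[N+](=O)[O-]"),
    label = c("active", "inactive", "active", "inactive")))
  irr <- alertLibrary("irritation")
  p1 <- profileDataset(x, irr)
  perm <- withr::with_seed(9, sample(4))
  p2 <- profileDataset(x[perm], irr)
  expect_equal(p1$per_alert, p2$per_alert)
  expect_equal(p1$set_ppv, p2$set_ppv)
  dup <- new("AlertLibrary",
             rules = rbind(alertRules(irr),
                           transform(alertRules(irr),
                                     alert_id = alert_id + 100)),
             endpoint = "irritation")
  p3 <- profileDataset(x, dup)
  expect_equal(p3$set_tp, p1$set_tp)
  expect_equal(p3$set_fp, p1$set_fp)
})

test_that("libraries round-trip through CSV and reject bad patterns", {
  irr <- alertLibrary("irritation")
  f <- tempfile(fileext = ".csv")
  writeAlertLibrary(irr, f)
  back <- readAlertLibrary(f)
  expect_equal(alertRules(back)$smiles, alertRules(irr)$smiles)
  tab <- alertRules(irr)
  tab$smiles[1] <- "C(((("
  g <- tempfile(fileext = ".csv")
  write.csv(tab, g, row.names = FALSE)
  expect_error(readAlertLibrary(g), "integrity")
})
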