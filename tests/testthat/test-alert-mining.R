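test_that("fragment enumeration respects the size window", {
  expect_length(enumerateFragments("CCC"), 0)          # below the floor
  expect_equal(enumerateFragments("CCCC"), "CCCC")     # single 4-chain
  expect_setequal(enumerateFragments("CCCCC"),
                  c("CCCC", "CCCCC"))                  # butyl + pentyl
  cfg <- miningConfig(minAtoms = 2, maxAtoms = 3)
  frs <- enumerateFragments("CCCCC", cfg)
  expect_setequal(frs, c("CC", "CCC"))
  sizes <- respiscreen:::.countHeavyAtoms(enumerateFragments(
    "CC(=O)OC(=O)CCCC", miningConfig()))
  expect_true(all(sizes >= 4 & sizes <= 20))
})

test_that("rings and multiple bonds survive fragmentation intact", {
  # every fragment of ethyl-cyclopentane containing a ring atom contains
  # the whole ring: the only valid cut is the exocyclic single bond
  frs <- enumerateFragments("CCC1CCCC1", miningConfig(minAtoms = 4))
  expect_setequal(frs, canonicalSmiles(
    c("C1CCCC1", "CC1CCCC1", "CCC1CCCC1")))
  # a carbonyl oxygen is never separated from its carbon: no fragment of
  # methyl propanoate contains the ester carbon without its =O
  frs2 <- enumerateFragments("CCC(=O)OC", miningConfig(minAtoms = 2))
  expect_true(canonicalSmiles("CC=O") %in% frs2)   # cuts C-C(=O): legal
  expect_true(canonicalSmiles("CC(=O)O") %in% frs2)
  expect_false(canonicalSmiles("CCO") %in% frs2)   # would strip the =O
  expect_false(canonicalSmiles("CCC") %in% frs2)   # ditto
  # aromatic rings stay whole too
  frs3 <- enumerateFragments("CCc1ccccc1", miningConfig(minAtoms = 4))
  expect_setequal(frs3, canonicalSmiles(
    c("c1ccccc1", "Cc1ccccc1", "CCc1ccccc1")))
})

test_that("fragment support counts molecules once each", {
  x <- toyPlantedSet(nA = 4, nI = 4)
  tab <- tabulateFragments(x)
  anh <- tab[tab$fragment == canonicalSmiles("CC(=O)OC(=O)C"), ]
  expect_equal(anh$n_active, 4)
  expect_equal(anh$n_inactive, 0)
  expect_equal(anh$precision, 1.0)
  expect_true(all(tab$n_active >= 4))
  strict <- tabulateFragments(x, miningConfig(minSupportActive = 5))
  expect_equal(nrow(strict), 0)

  # two occurrences in one molecule count once
  one <- MoleculeSet(data.frame(
    record_id = c("d", "i"),
    smiles = c("CC(=O)OC(=O)CCCC(=O)OC(=O)C", "CCCCCC"),
    label = c("active", "inactive")))
  t1 <- tabulateFragments(one, miningConfig(minSupportActive = 1))
  anh1 <- t1[t1$fragment == "CC(=O)O", ]
  expect_equal(anh1$n_active, 1)
})

test_that("greedy extraction meets its definitional guarantees", {
  allIna <- MoleculeSet(data.frame(
    record_id = c("i1", "i2"), smiles = c("CCCCCC", "CCOCC"),
    label = "inactive"))
  expect_warning(lib0 <- extractAlerts(allIna), "no active")
  expect_equal(length(lib0), 0)

  x <- toyPlantedSet(nA = 5, nI = 5)
  lib <- extractAlerts(x)
  rules <- alertRules(lib)
  expect_gt(nrow(rules), 0)
  expect_equal(rules$ppv, rules$n_true / rules$n_tot)
  m <- matchAlerts(x, lib)
  labs <- moleculeLabels(x)
  # per-rule n_true/n_tot agree with fresh matching on the full set
  expect_equal(as.integer(colSums(m)), rules$n_tot)
  expect_equal(as.integer(colSums(m & labs == "active")), rules$n_true)
  # union of rules covers every active counted in n_true
  expect_equal(sum(rowSums(m)[labs == "active"] > 0), 5)
  # determinism: identical input and config give identical rules
  lib2 <- extractAlerts(x)
  expect_identical(alertRules(lib2), rules)
})

test_that("mined rules satisfy the size and support constraints", {
  d <- generateDataset(generatorConfig(
    nActive = 12, nInactive = 12, motifPool = benchmarkMotifs(),
    motifsPerDataset = 3, seed = 77))
  lib <- extractAlerts(d$molecules)
  rules <- alertRules(lib)
  expect_gt(nrow(rules), 0)
  sizes <- respiscreen:::.countHeavyAtoms(rules$smiles)
  expect_true(all(sizes >= 4 & sizes <= 20))
  expect_true(all(rules$n_true >= 4))
  rec <- motifRecovery(lib, d$molecules, d$motifs)
  expect_true(all(rec))
})
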