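test_that("CSV, SMILES and SDF inputs parse into records", {
  csv <- tempfile(fileext = ".csv")
  write.csv(data.frame(id = c("mol1", "mol2"),
                       smiles = c("CCO", "not_a_smiles"),
                       label = c("inactive", "active")),
            csv, row.names = FALSE)
  suppressMessages(x <- parseStructures(csv))
  df <- moleculeData(x)
  expect_equal(nrow(df), 2)
  expect_equal(df$smiles[1], "CCO")
  expect_equal(df$label, c("inactive", "active"))
  expect_true(is.na(df$smiles[2]))  # unparsable kept, not dropped

  bad <- tempfile(fileext = ".csv")
  write.csv(data.frame(structure = "CCO"), bad, row.names = FALSE)
  expect_error(parseStructures(bad), "SMILES column")

  empty <- tempfile(fileext = ".smi")
  writeLines(character(0), empty)
  expect_warning(e <- parseStructures(empty), "empty")
  expect_equal(length(e), 0)

  smi <- tempfile(fileext = ".smi")
  writeLines(c("CCO ethanol", "c1ccccc1 benzene"), smi)
  y <- parseStructures(smi)
  expect_equal(moleculeData(y)$record_id, c("ethanol", "benzene"))

  sdfFile <- tempfile(fileext = ".sdf")
  sdf <- suppressWarnings(
    ChemmineR::smiles2sdf(c(a = "CCO", b = "CCC", c = "CCN")))
  ChemmineR::write.SDF(sdf, sdfFile)
  z <- parseStructures(sdfFile)
  expect_equal(length(z), 3)
  expect_false(anyNA(moleculeData(z)$smiles))
})

test_that("curation desalts, neutralizes, and rejects by category", {
  x <- MoleculeSet(data.frame(
    record_id = paste0("m", 1:7),
    smiles = c("CC(=O)[O-].[Na+]",   # salt -> acetic acid
               "O=[Si]=O",           # inorganic (no carbon)
               "CC[Sn](CC)(CC)CC",   # organometallic
               "CCO.CCC",            # mixture of two organics
               NA,                   # unparsable
               "C[NH3+].[Cl-]",      # salt of a cation -> methylamine
               "CCOC(C)C")))         # already clean
  cur <- curateStructures(x)
  df <- moleculeData(cur$molecules)
  expect_equal(df$record_id, c("m1", "m6", "m7"))
  expect_equal(df$smiles[df$record_id == "m1"], canonicalSmiles("CC(=O)O"))
  expect_equal(df$smiles[df$record_id == "m6"], canonicalSmiles("CN"))
  r <- cur$report
  expect_equal(r$n_rejected_mixture, 1)
  expect_equal(r$n_rejected_inorganic, 1)
  expect_equal(r$n_rejected_organometallic, 1)
  expect_equal(r$n_unparsable, 1)
  expect_equal(r$n_output,
               r$n_input - r$n_rejected_mixture - r$n_rejected_inorganic -
                 r$n_rejected_organometallic - r$n_unparsable -
                 r$n_duplicates_merged)
  # every record lands in exactly one category or the output
  expect_equal(sum(cur$log$category != "ok") + r$n_output, r$n_input)
  # dedup keys identify identical standardized structures
  expect_match(df$dedup_key[1], "^[A-Z]{14}-[A-Z]{10}-[A-Z]$")
})

test_that("net-zero charged species are kept as-is", {
  x <- MoleculeSet(data.frame(
    record_id = c("nitro", "zwit"),
    smiles = canonicalSmiles(c("[O-][N+](=O)CC", "C(C(=O)[O-])[NH3+]"))))
  cur <- curateStructures(x)
  df <- moleculeData(cur$molecules)
  # nitro group survives untouched (it is itself an alert substructure)
  expect_equal(sort(respiscreen:::.smilesElements(df$smiles[1])),
               sort(c("C", "C", "N", "O", "O")))
  expect_true(grepl("\\+", df$smiles[1]))
  expect_true(grepl("\\+", df$smiles[2]))  # zwitterion unchanged
  expect_true(any(grepl("kept as-is", cur$log$note)))
})

test_that("curation is idempotent", {
  x <- MoleculeSet(data.frame(
    record_id = paste0("m", 1:4),
    smiles = c("CC(=O)[O-].[Na+]", "CCO", "c1ccccc1O", "C[NH3+].[Cl-]")))
  once <- curateStructures(x)
  twice <- curateStructures(once$molecules)
  expect_equal(moleculeData(twice$molecules)$smiles,
               moleculeData(once$molecules)$smiles)
  expect_equal(twice$report$n_output, once$report$n_output)
})

test_that("deduplication merges by key with positive-wins labels", {
  x <- MoleculeSet(data.frame(
    record_id = c("r1", "r2", "r3", "r4"),
    smiles = c("CCO", "CCO", "CCO", "CCC"),
    dedup_key = c("K1", "K1", "K1", "K2"),
    label = c("inactive", "active", "inactive", "inactive")))
  d <- deduplicateStructures(x)
  df <- moleculeData(d$molecules)
  expect_equal(d$n_merged, 2)
  expect_equal(df$label[df$dedup_key == "K1"], "active")
  expect_equal(df$label[df$dedup_key == "K2"], "inactive")

  # identical labels merge quietly
  y <- MoleculeSet(data.frame(record_id = c("a", "b"),
                              smiles = c("CCO", "OCC"),
                              dedup_key = c("K", "K"),
                              label = c("inactive", "inactive")))
  expect_equal(moleculeData(deduplicateStructures(y)$molecules)$label,
               "inactive")

  # distinct writings of one structure share a canonical key end-to-end
  z <- curateStructures(MoleculeSet(data.frame(
    record_id = c("w1", "w2"), smiles = canonicalSmiles(c("OCC", "CCO")))))
  expect_equal(length(deduplicateStructures(z$molecules)$molecules), 1)
})

test_that("dedup output is order-independent", {
  base <- data.frame(
    record_id = paste0("r", 1:6),
    smiles = rep(c("CCO", "CCC", "CCN"), 2),
    dedup_key = rep(c("K1", "K2", "K3"), 2),
    label = c("inactive", "active", "unlabeled",
              "active", "inactive", "inactive"))
  ref <- NULL
  for (seed in 1:5) {
    perm <- withr::with_seed(seed, sample(nrow(base)))
    d <- deduplicateStructures(MoleculeSet(base[perm, ]))
    pairs <- moleculeData(d$molecules)[, c("dedup_key", "label")]
    pairs <- pairs[order(pairs$dedup_key), ]
    rownames(pairs) <- NULL
    if (is.null(ref)) ref <- pairs else expect_equal(pairs, ref)
  }
})

test_that("curated sets and reports round-trip through files", {
  x <- MoleculeSet(data.frame(record_id = "m1", smiles = "CCO",
                              label = "active"))
  cur <- curateStructures(x)
  f <- tempfile(fileext = ".csv")
  writeCuratedSet(cur$molecules, f)
  back <- read.csv(f, stringsAsFactors = FALSE)
  expect_equal(back$smiles, "CCO")
  g <- tempfile(fileext = ".json")
  writeCurationReport(cur$report, g)
  expect_equal(jsonlite::read_json(g)$n_output, 1)
})
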