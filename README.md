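# respiscreen

Structural alerts and consensus machine learning for respiratory-toxicity
screening in R.

Inhaled chemicals can irritate the respiratory tract (GHS STOT-SE
Category 3, hazard code H335) or sensitize it (GHS Category 1, H334).
Neither endpoint has an approved in vitro assay, and negative data are
scarce, so hazard triage of chemical inventories leans on in silico
methods. `respiscreen` is for toxicologists and cheminformaticians who
need to screen SMILES lists for these endpoints: it combines
substructure-based structural alerts with a consensus QSAR classifier
and reports, per chemical, how strongly the two lines of evidence agree.

## What it computes

* **Alert profiling.** Packaged libraries of 13 respiratory-irritation
  and 18 respiratory-sensitization alerts (plain-SMILES substructure
  queries with their source occurrence counts), matched by Open Babel
  substructure search. An alert set's quality on a labeled dataset is its
  positive predictive value, PPV = TP / (TP + FP), over molecules
  matching at least one alert.
* **Alert mining.** Data-driven extraction of new alerts from a labeled
  set: all fragments of 4–20 heavy atoms (rings and multiple bonds kept
  intact) supported by ≥ 4 actives, selected by precision-ranked greedy
  covering of the actives.
* **Consensus classification.** N base models (fingerprint/physchem
  featurizers x forest/boosting/linear learners) are averaged:
  ȳ_j = (1/N) Σ_m y_jm, with disagreement
  CONS-STD_j = sqrt((1/N) Σ_m (ȳ_j − y_jm)²). Molecules whose CONS-STD
  exceeds a threshold calibrated by 5-fold cross-validation are outside
  the applicability domain and called Inconclusive. Performance is
  reported as ACC, SEN, SPE and rank-based AUC.
* **Integrated confidence score.** Alert call x model call →
  2 (both Active), 1 (one Active, one Inconclusive), 0 (both
  Inconclusive), −1 (alerts Active, model Inactive), NA (no alert, model
  Inactive).
* **Synthetic benchmarks.** A generator that grafts alert substructures
  onto alert-free scaffolds at controlled noise rates, so mining,
  modeling and screening are all testable with exact ground truth and no
  external data.

## Worked example

```r
library(respiscreen)

# 1. curate a small list
x <- MoleculeSet(data.frame(
  record_id = c("acetic_anhydride", "sodium_acetate", "silica", "hexane"),
  smiles = c("CC(=O)OC(=O)C", "CC(=O)[O-].[Na+]", "O=[Si]=O", "CCCCCC")))
cur <- curateStructures(x)
cur$report
#> CurationReport
#>   n_input                    4
#>   n_rejected_mixture         0
#>   n_rejected_inorganic       1
#>   n_rejected_organometallic  0
#>   n_unparsable               0
#>   n_duplicates_merged        0
#>   n_output                   3
```

Silica is rejected (no carbon); sodium acetate is desalted and
neutralized to acetic acid. Acetic anhydride matches irritation alert #1
(anhydrides):

```r
irr <- alertLibrary("irritation")
which(matchAlerts(cur$molecules, irr)["acetic_anhydride", ])
#> 1
#> 1
```

Train a consensus model on a synthetic benchmark and screen the curated
list:

```r
d <- generateDataset(generatorConfig(nActive = 60, nInactive = 60,
     motifPool = benchmarkMotifs(), motifsPerDataset = 3, seed = 1))
model <- trainConsensus(d$molecules, seed = 1)
model
#> ConsensusModel with 5 base models
#>   AD threshold (CONS-STD): 0.2619
#>   - fp2 x rf
#>   - maccs x xgb
#>   - ap x rf
#>   - physchem x xgb
#>   - physchem x glmnet

rep <- screenChemicals(cur$molecules, irr, model)
rep$results[, c("record_id", "alert_call", "ml_call",
                "confidence_score", "final_category")]
#>          record_id   alert_call      ml_call confidence_score     final_category
#> 1 acetic_anhydride       Active       Active                2    Likely-toxicant
#> 2   sodium_acetate Inconclusive Inconclusive                0         Unresolved
#> 3           hexane Inconclusive     Inactive               NA Predicted-inactive
```

Score 2 means both lines of evidence flag the chemical — acetic
anhydride carries the anhydride alert *and* the model (trained here on a
benchmark that plants that motif) calls it active. Hexane carries no
alert and the model calls it inactive, the lowest-priority outcome.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/respiscreen` with subcommands `curate`, `profile`, `mine`,
`simulate`, `train`, and `screen`.

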