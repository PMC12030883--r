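---
title: "Screening chemicals for respiratory irritation and sensitization: methods"
author: "respiscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening chemicals for respiratory irritation and sensitization: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The screening problem

Respiratory irritation (GHS STOT-SE Category 3, hazard code H335) and
respiratory sensitization (GHS Category 1, H334) are endpoints with no
approved in vitro assay, little negative data, and far more chemicals in
commerce than could ever be tested in vivo. The practical question is
triage: given a list of structures, which ones deserve experimental
follow-up first? `respiscreen` answers it with two complementary lines of
in silico evidence and an explicit account of their agreement:

1. **Structural alerts** — substructures whose presence in a molecule is
   statistically associated with activity. Alerts are transparent and
   cheap, but the absence of an alert is not evidence of inactivity.
2. **A consensus machine-learning classifier** — several base models over
   different molecular representations, averaged, with an applicability
   domain that withholds judgement when the base models disagree.
3. **A confidence score** combining the two calls, so a reviewer can see
   at a glance whether a flag rests on one line of evidence or two.

# Data curation

All structure handling goes through Open Babel (via ChemmineR/ChemmineOB).
`curateStructures()` applies the standard QSAR-ready cleanup in a fixed
order, and the order matters:

* **Desalting first.** Components without carbon are counterions and are
  stripped; sodium acetate becomes acetic acid. Only then is the metal
  check applied, so genuine single-component organometallics
  (tetraethyltin, ferrocene-like species) are rejected while simple salts
  of organics survive.
* **Mixture rule.** A structure with two *distinct* carbon-containing
  components after desalting is a mixture and is rejected; repeated
  identical components collapse to one.
* **Element whitelist.** Retained organics may contain only H, B, C, N,
  O, F, Si, P, S, Cl, Se, Br, I. Si is deliberately on the list: one of
  the packaged irritation alerts is a chlorosilane. Anything else is
  rejected as inorganic (no carbon) or metallo-organic (carbon plus a
  disallowed element).
* **Charge neutralization moves net charge toward zero only.** Anionic
  acids are protonated and protonated amines deprotonated, but net-neutral
  charge-separated groups are never touched. This is what protects nitro
  groups — `[O-][N+](=O)C` is itself a packaged alert — and zwitterions,
  which are kept as-is and logged. A rewrite that fails to re-parse is
  abandoned and logged, never silently applied.
* **Deduplication** uses the Open Babel InChIKey of the standardized
  structure as the key. When duplicates disagree on the label, the
  survivor is labeled active: negative calls in the source databases are
  usually based on weaker, indirect evidence, so a positive anywhere
  wins.

Every input record ends in exactly one place — the curated output or one
rejection category — and `CurationReport` totals are checked by the test
suite as an invariant, not assumed.

# The packaged alert libraries

`alertLibrary()` ships 13 respiratory-irritation and 18
respiratory-sensitization alerts as plain-SMILES substructure queries,
with their occurrence counts in the source data (`n_tot` in all
molecules, `n_true` in actives) and the positive predictive value
`ppv = n_true / n_tot`. Two transcription decisions:

* Whitespace inside patterns in the published table (an extraction
  artifact, e.g. `O = C = N...`) is stripped; everything else, including
  one phthalate-diester rule whose own PPV (8/13 = 0.62) sits far below
  the set-level 0.92, is kept exactly as published. No per-rule PPV floor
  is imposed on the packaged rules.
* Patterns are interpreted as written: element and bond-order
  constraints, aromatic atoms aromatic, and **no** added hydrogen-count
  or degree constraints. A molecule matching an alert twice counts once —
  occurrence statistics count chemicals, not matches. All 31 patterns
  compile verbatim as Open Babel SMARTS; no rewrites were needed.

`profileDataset()` recomputes per-alert counts on any labeled set and the
set-level confusion: a molecule is flagged if it matches at least one
alert, `set_ppv = set_tp / (set_tp + set_fp)`. PPV with a zero
denominator is reported as undefined (`NA`), never coerced to 0 or 1.

# Mining new alerts

`extractAlerts()` reimplements data-driven alert extraction in the SARpy
tradition: enumerate substructures, count support, select rules.

**Fragmentation scheme.** A fragment is a connected subgraph whose
boundary bonds are all acyclic single non-aromatic bonds. Equivalently:
rings survive intact and multiple bonds are never cut, and broken single
bonds become unconstrained attachment points, so a fragment matches any
molecule containing it as a subgraph. Implementation: contract every
uncuttable bond to get "rigid units", then enumerate all connected unit
subsets (an ESU-style enumeration that visits each subset exactly once,
pruned at the 20-heavy-atom ceiling), and write each subset back out as a
canonical SMILES via Open Babel. The test suite checks this enumerator
against an independent brute-force oracle that tries every atom subset of
every molecule up to 8 heavy atoms.

**Defaults** follow the published protocol: fragments of 4–20 heavy
atoms, support in at least 4 active compounds. The minimum-precision
floor (default 0.8) is this package's own selection knob — the original
tool's internal criterion is unpublished — and it is exposed everywhere a
user can mine.

**Support counting.** A molecule "contains" a candidate fragment iff the
fragment appears in the molecule's own enumerated fragment set; this is
exact under the fragmentation scheme and avoids a full
fragments x molecules substructure search during mining. Emitted rules
then get `n_tot`/`n_true`/`ppv` recomputed by real substructure matching
on the full input set, so the reported numbers never depend on that
shortcut.

**Selection** is greedy covering with a total order: precision, then
active support, then smaller size, then lexicographic canonical text.
Support and precision are re-evaluated on the actives not yet covered
(inactive counts stay fixed); selection stops when no fragment meets both
floors. The total tie-break makes mining fully deterministic.

**Recovery is judged by match sets, not text.** A planted motif counts as
recovered when some mined rule matches exactly the same actives as the
motif itself — a sub-fragment with identical coverage is an equally valid
alert. The recovery benchmark uses `benchmarkMotifs()`, eight packaged
patterns chosen pairwise structurally disjoint (no shared fragment of 4+
heavy atoms). With overlapping motifs (two aliphatic-acid alerts sharing
a `CCC(=O)O` core, say) a shared sub-fragment can legitimately cover both
motifs' actives at once and ground truth becomes ambiguous; that is a
property of the covering problem, not of the miner.

# The consensus classifier

Base models are featurizer x learner pairs. Featurizers: Open Babel FP2
path fingerprints (1024 bits), MACCS keys, atom-pair fingerprints folded
to 512 bits, and a small physicochemical block (MW, logP, TPSA, H-bond
counts, molar refractivity, heavy-atom and aromatic-atom counts).
Learners: random forest, gradient boosting, ridge-penalized logistic
regression. The default menu pairs five complementary members, mirroring
the five-model irritation and four-model sensitization consensus of the
published study; the platform-specific descriptor packages and neural
learners used there are intentionally not reproduced.

Each base model outputs the probability of the Active class; the
consensus output for molecule *j* is the mean over the *N* members, and
the disagreement is

CONS-STD_j = sqrt( (1/N) * sum_m (ybar_j − y_jm)^2 )

(the 1/N normalization, so two models at 0 and 1 give exactly 0.5).
Averaging probabilities rather than votes keeps CONS-STD continuous and
loses no information; the decision threshold on the mean is 0.5.

**Applicability domain.** The published scheme gives no numeric CONS-STD
cutoff, so the package calibrates one: the 95th percentile of
out-of-fold CONS-STD values from stratified 5-fold cross-validation on
the training set. About 5% of training-like molecules therefore fall
outside the domain and are called Inconclusive; the quantile is a config
knob and the threshold is stored in the model artifact. Molecules that
cannot be featurized at all are Inconclusive with the reason logged,
never silently dropped.

Splits and folds are stratified by label and fully seed-determined; all
learner randomness flows from the same seed, so identical inputs give
identical models. Optional greedy forward selection on cross-validated
AUC ("include a member if it improves the consensus") exists but is off
by default: all configured members are used.

Evaluation uses the standard confusion-matrix statistics
(ACC, SEN, SPE) with undefined ratios reported as `NA`, plus rank-based
AUC with ties counted 1/2 — the probability a random active outscores a
random inactive. The test suite cross-checks the AUC implementation
against pROC.

# The confidence score

Alert-based prediction has no "Inactive" state: no alert means no
evidence. The integration is therefore:

| alerts       | model        | score | category           |
|--------------|--------------|------:|--------------------|
| Active       | Active       |     2 | Likely-toxicant    |
| Active       | Inconclusive |     1 | Possible-toxicant  |
| Inconclusive | Active       |     1 | Possible-toxicant  |
| Inconclusive | Inconclusive |     0 | Unresolved         |
| Active       | Inactive     |    -1 | Conflict           |
| Inconclusive | Inactive     |    NA | Predicted-inactive |

The last row has no published score. Rather than overload 0 (reserved
for double-Inconclusive), the package reports `NA` /
Predicted-inactive, preserving the four published scores exactly while
keeping the mapping total. `screenChemicals()` asserts the set-algebra
identities (score-2 set = alert-Active ∩ model-Active, count
conservation across all five categories) on every run.

# The synthetic-data generator

Real GHS/ECHA/NITE compilations cannot be shipped, so the generator
builds benchmark sets with exact ground truth. Actives are alert-free
scaffolds — a packaged pool of ~30 small hydrocarbons and aliphatic
ethers, verified against both alert tables in the test suite — with a
motif grafted through one single bond at a valence-checked, seed-chosen
attachment point; the motif therefore survives as a subgraph by
construction, and every graft is verified by an actual substructure
match before acceptance. Inactives are motif-free (decorated) scaffolds.
Planting noise leaves `round(noise * n_active)` actives motif-free;
decoy noise plants motifs into inactives. The manifest records every
molecule's planted motif, and generation is byte-identical for a given
config.

What the generator does *not* emulate: the skewed chemical-space
distribution of real regulatory datasets, activity cliffs, label noise
from heterogeneous assay evidence, or mixtures/salts (its output is
curation-clean by construction). Passing the planted-recovery and
consensus benchmarks therefore shows the machinery is correct and
self-consistent — it does not certify real-world accuracy, which in the
published study rests on compiled datasets that are not public.

`generateFeatureSeparableSet()` serves the model-level tests: actives
drawn from chlorinated aromatics, inactives from aliphatic scaffolds, so
the families are trivially separable by fingerprints at separation 1 and
carry no label signal at separation 0 (the family becomes a coin flip).

# Problem sizes and numerical choices

The shipped tests and the acceptance script run at deliberately modest
sizes, chosen as the smallest at which the properties are meaningful
rather than as estimates of real-data performance: mining recovery uses
24 actives + 24 inactives (3 motifs, 8 actives each, 5% planting noise)
over 10–20 seeds; the consensus benchmark uses 400 molecules with an
80/20 split over 10 seeds; separable-set checks use 60–100 molecules.
Other fixed choices: stratified splits allocate `round(f*N)` to training
with largest-remainder rounding across classes; fold assignment is
round-robin within class after a seeded shuffle; tie handling in AUC is
the standard 1/2 convention; hydrocarbon-only scaffolds are used for
mining benchmarks so graft junctions cannot create incidental
heteroatom-containing substructures.

# Known limitations

* Substructure semantics are Open Babel SMARTS semantics; exotic aromatic
  systems (e.g. pyrrole-type fragments written without hydrogen counts)
  can fail to re-parse and such fragments are skipped during mining, with
  aromaticity read from Open Babel's canonical SMILES rather than
  perceived independently.
* The miner's candidate support uses fragment-set containment, which for
  a ring-containing molecule does not see a purely acyclic fragment
  embedded inside a ring (matching semantics would); final rule
  statistics are immune because they are recomputed by substructure
  search.
* Tautomers are not enumerated and stereochemistry is not normalized
  beyond the canonical form, matching the curation scope.
* The consensus is only as good as its features: planted-motif benchmarks
  are nearly linearly separable in fingerprint space, which is exactly
  why they validate the machinery rather than estimate real screening
  accuracy.
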