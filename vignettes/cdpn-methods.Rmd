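---
title: "Constructing debiased compound-protein interaction datasets with cdpn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing debiased compound-protein interaction datasets with cdpn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdpn)
library(data.table)
```

## The problem

Public bioactivity repositories (ChEMBL, BindingDB, PubChem BioAssay) are the
raw material for sequence-based compound-protein interaction (CPI) models
used in virtual screening. Two structural biases make models trained
directly on them look better than they are:

* **Label-distribution bias.** Medicinal chemists mostly publish actives, so
  for many targets the positive prevalence — the fraction of positive records
  among all records for the target — is close to 1. A model can score near
  the top of every benchmark by learning *which targets are popular*, not
  which compounds bind; at screening time it then assigns inflated scores to
  everything, and the top decile of a ranked library becomes uninformative.
* **Analogue (scaffold) bias.** Series of near-duplicate compounds around a
  favoured scaffold are heavily over-represented, so a model is repeatedly
  rewarded for memorising one chemotype.

`cdpn` implements a dataset-construction protocol that attacks both biases
with three phases — cluster-capped down-sampling, putative-negative
augmentation, and time/scenario splitting — preceded by conventional
curation, plus the diagnostics used to verify the result (positive
prevalence, BEDROC, enrichment factors, attention-vs-pocket overlap).

## Curation

Records are kept only if their activity unit is comparable on the pChEMBL
scale (`Potency`, `Ki`, `Kd`, `IC50`, `AC50`, `EC50`, `ED50`, `XC50`).
Values arrive in nanomolar; `compute_pchembl()` maps them to
$\mathrm{pChEMBL} = -\log_{10}(\text{value in M}) = 9 - \log_{10}(\text{value in nM})$,
and a pair is labeled positive when pChEMBL $\ge 6$, i.e. activity at or
below 1000 nM. The threshold side is a convention: the boundary value is
labeled positive here, and the threshold is a parameter.

Drug-likeness keeps compounds with no metal atoms, molecular weight
strictly below 1000 Da and strictly more than 12 heavy atoms — deliberately
looser than Lipinski so that informative chemistry is retained while
inorganic and fragment-sized entries are not. Frequent hitters (known
colloidal aggregators and luciferase inhibitors, supplied as blocklists)
with at least one positive record are removed; by default *all* their
records go, since an apparent negative of a promiscuous aggregator is no
more trustworthy than its positives (a positives-only mode is available).
Finally, duplicates collapse to one row per (compound, target) pair keeping
the earliest year — a stable choice that makes the later time split
independent of row order — and pairs reported with both labels by different
sources are removed outright.

## Chemical-space clustering

Analogue bias and putative-negative eligibility are both defined in terms
of *chemical clusters*. Compounds are represented as fixed-length
substructure-key bit vectors (881-bit PubChem keys in the published
datasets; the length is free here and the synthetic generator uses 128 bits
purely for speed). A pool representative of chemical space is drawn by
*complexity-stratified sampling*: compounds are binned into (by default)
100 classes by their circular-fingerprint on-bit count — a proxy for
substructure complexity — and sampled proportionally per class with
largest-remainder rounding, so the complexity histogram is preserved.
Binning is equal-frequency; when fewer distinct on-bit counts than classes
exist, each count forms its own class.

The bit matrix is centred and projected onto the smallest PCA basis
retaining 95% of total variance, and seeded Lloyd k-means (k-means++
initialisation, empty clusters re-seeded at the farthest point) partitions
the projected space into `K` clusters. The published protocol uses
`K = 75745` over 9.5 million compounds; `K` is a configuration value and
the test suite exercises small `K`. `assign_cluster()` gives any compound
the id of its nearest centroid, ties to the lowest id.

## Cluster-capped down-sampling

Two passes, both with cap 3:

1. records of **multi-target compounds** (≥ 2 distinct targets) are capped
   per (target, cluster) — these compounds are retained preferentially
   because multi-target dose-response data reduce sparsity;
2. the remaining records are capped per (target, cluster, label).

Within an over-full group the retained rows are a uniform seeded draw. The
per-group permutation is generated from a seed mixed with the group key, so
the outcome is independent of row order and raising a cap only ever adds
rows. One subtlety: a single application of the two passes is not a
projection — capping can demote a compound to single-target status, and its
surviving rows may then overflow a label-aware group if the procedure is
re-applied. `run_downsampling()` therefore iterates the two-pass procedure
to its fixed point (row counts strictly shrink, so this terminates, in
practice after one or two extra passes); the result satisfies both cap
systems simultaneously and re-applying the operation is the identity.

## Putative-negative augmentation

Experimentally unmeasured pairs are added as *putative negatives* (PN) —
never putative positives, which cannot be asserted without experiments. The
amount of augmentation is controlled by the rectified half sigmoid

$$\alpha(x) = \max\!\left(x,\; \frac{2 - 2m}{1 + e^{-g\,(x - 1)}} + m\right),
\qquad g = 3,\; m = 0.4,$$

which maps an observed imbalance $x$ to a post-sampling negative ratio, and
the quota

$$N^{PN} = \max\bigl(0,\; \operatorname{round}(\alpha \cdot N^P - N^N)\bigr).$$

$\alpha$ is continuous, non-decreasing, fixes $\alpha(1) = 1$ and equals
$x$ wherever the data are already balanced, so balanced entities are left
untouched; the clamp at zero guarantees that entities with negative
prevalence $\ge 0.5$ receive nothing. The rounding rule (half-up) is a
convention of this implementation.

* **Stage 1 — PN compounds for targets.** Targets with only positive
  records, or with positive:negative ratio at least 2:1, receive PN
  compounds. Here $x$ is the target-level negative prevalence
  $N^N/(N^P+N^N)$. Sources are clusters with *no recorded interaction with
  the target*, preferring clusters whose records are positive-only
  dataset-wide (the two-tier rule; a flat interaction-free mode is a flag).
  Clusters are visited in seeded random order, at most 3 compounds per
  cluster, until the quota is met — this spreads the synthetic negatives
  across chemotypes instead of piling them into one series. An unmet quota
  is a warning, not an error. Note that the 2:1 trigger and the quota are
  independent gates: a target at exactly 2:1 is selected but its quota can
  round to zero (e.g. 10 positives / 5 negatives), in which case no row is
  added.
* **Stage 2 — PN targets for compounds.** Proteins are grouped into six
  families (Kinase, Nonkinase Enzyme, Nuclear Receptor, Membrane Receptor,
  Ion Channel, Others); a compound is assumed highly unlikely to bind
  families it shares no recorded interaction with. Compounds with at least
  one positive record and fewer than six touched families receive PN
  targets from the untouched families, with $x$ the compound-level
  negative:positive ratio and counts recomputed *after* stage 1 so the two
  stages do not double-correct. Candidate targets that are already
  negative-dominant ($N^N \ge N^P$) are excluded as recipients — routing a
  synthetic negative to them would alter entities the protocol promises to
  leave unchanged.

Measured rows pass through augmentation bit-identical; every added row
carries `provenance = "putative"`, a negative label, and a sentinel `NA`
year so it can never be mistaken for a dated measurement. Family
eligibility is always evaluated on measured rows, and both samplers refuse
to duplicate an existing pair, so (compound, target) stays unique.

## Time split and screening scenarios

Measured rows dated strictly before a per-family cutoff year (default
2015; the published datasets vary the cutoff per family with record
volume) form the training set; later rows form validation. Putative rows
go to training only. Validation is cross-classified by whether the target
occurs in training (*seen target*) and whether the compound's cluster
occurs in training (*seen cluster*):

| scenario | emulates |
|---|---|
| seen target / seen cluster | drug repurposing |
| seen target / unseen cluster | novel lead discovery |
| unseen target / seen cluster | novel target, known chemistry |
| unseen target / unseen cluster | fully cold start |

Seen-ness is computed on the post-augmentation training set, so putative
rows count toward it — a deliberate choice (they are part of what the model
sees) exposed by the data layout rather than a flag.

## Diagnostics and screening metrics

* `positive_prevalence()` per target or cluster is the primary bias
  readout: the protocol should move near-1 prevalences toward ~0.5-0.7 and
  leave negative-dominant entities untouched.
* `bedroc()` implements the Boltzmann-enhanced discrimination of ROC with
  the early-recognition weight $\alpha = 80.5$. The implementation min-max
  normalises the discrete sum $\sum_i e^{-\alpha r_i / N}$ over active
  ranks between the worst and perfect rankings, so a perfect ranking scores
  exactly 1 and the worst exactly 0 at any list size; the familiar
  closed-form normalisation is a continuous approximation and is not used.
  Score ties are broken by a seeded shuffle: deterministic yet unbiased.
* `enrichment_factor()` is the active rate in the top `ceiling(f·N)` picks
  over the global active rate (EF1% by default).
* `top_decile_scores()` summarises the top 10% of per-entity screening
  scores — inflated medians here are the signature of prevalence bias.
* `attention_pocket_eval()` compares high-attention residues with annotated
  binding-pocket masks via coverage (recall) and IoU. How attention weights
  are binarised is not standardised; the default selects the top-k residues
  with k equal to the pocket size, with a quantile-threshold rule as the
  alternative, and coverage always bounds IoU from above.

## The synthetic world

Everything is testable offline through `generate_synth_bundle()`, which
emulates the *structure* the protocol assumes, not real chemistry:

* compounds planted in clusters via cluster-specific signature bits
  (background on-bit rate 0.05, signature rate 0.9), so k-means can recover
  the partition;
* per-target positive prevalence drawn from Beta(5, 1) (mean 5/6), the
  positive-skew regime the protocol is designed to correct;
* each target's compounds drawn from a small per-target set of clusters
  (8 of 50 by default) — the analogue concentration of real screening
  series, and the reason cluster-based PN eligibility has room to work;
* the defaults 200 targets, 5,000 compounds, 50-150 records per target
  (~20,000 records) form the standard desk-scale bundle;
* duplicates, label conflicts, drug-likeness violations and years spanning
  the split cutoff injected at configured rates, with activity values always
  on the correct side of 1000 nM for the intended label.

A green test on this world establishes that the machinery is correct — the
filters, quotas, eligibility rules, caps, splits and metrics do what they
claim. It does not establish that models trained on the debiased output
generalise better; that claim needs real data and trained models, which are
out of scope here.

## Numerical conventions and edge cases

* All randomness flows from one global seed through
  `derive_seed(seed, stage, ...)` (a 31-bit string-mix hash), so stages are
  independently reproducible and adding a stage never perturbs another.
* Quota rounding is half-up, clamped at zero; the labeling boundary
  (pChEMBL = 6) is positive; down-sampling caps are inclusive.
* k-means re-seeds an empty cluster at the point farthest from its
  centroid; nearest-centroid ties go to the lowest cluster id; PCA drops
  numerically-zero components so a variance target of 1 returns the rank.
* Degenerate inputs fail loudly: constant fingerprint matrices, all-zero
  attention weights, label vectors without both classes, non-positive
  activity values, measured rows without a year.
* A compound touching all six families, or a target touching every cluster,
  simply receives no putative rows.

## Worked example

```{r example, eval = FALSE}
bundle <- generate_synth_bundle(synth_config(seed = 7))
run <- run_cdpn(bundle$records, bundle$compounds,
                cdpn_config(K = 50, seed = 7))
print(run)
#> cdpn pipeline run
#>   curated pairs:        19161
#>   after down-sampling:  7743
#>   putative negatives:   3349
#>   final dataset:        11092 (58.02% positive)
#>   targets with prevalence > 0.80: 127 -> 0
```

The run is byte-reproducible under its seed; the report reconciles row
counts (`balanced = downsampled + putative`) and records per-target
prevalence before and after augmentation.

## Known limitations

* The synthetic generator does not emulate realistic molecular property
  distributions, assay noise models, or inter-target correlation beyond
  cluster sharing.
* PN rows are assumptions, not measurements: a cluster or family with no
  recorded interaction is *probably* inactive against the entity being
  balanced, and the false-negative rate of that assumption is untested
  here.
* The published cluster count (75,745) and per-family cutoff years are not
  reproduced; both are configuration values.
* Affinity-valued (regression) augmentation is out of scope.
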