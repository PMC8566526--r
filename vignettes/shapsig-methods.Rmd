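---
title: "Explaining dual-target compound predictions with exact Shapley values"
author: "ShapSig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Explaining dual-target compound predictions with exact Shapley values}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific question

Polypharmacology asks which structural features allow a compound to engage
two pharmacological targets at once. Given a target pair, compounds with
curated activity against both targets (dual-target compounds, DT) can be
contrasted with compounds active against exactly one of the two
(single-target compounds, ST). A classifier that separates the two classes
from chemical structure alone proves that distinguishing features exist;
an *explanation* of that classifier can reveal what those features are.
ShapSig implements this complete analysis: curation of ChEMBL-style
bioactivity tables, a collision-free circular-substructure representation,
balanced random forest (BRF) classification, exact per-compound Shapley
value (SV) attribution, and a rank-based scheme that distils the
attributions into a small set of prioritized features which are mapped back
onto compound structures.

Because a curated public bioactivity extract cannot be shipped, the package
pairs the analysis with a first-class synthetic data generator that plants
known structural motifs into a realistic two-target-pair system. The
generator defines the study conditions under which every end-to-end claim
of the package is tested; what passing those tests does and does not say
about real data is discussed at the end.

# Data curation

Raw activity records carry the fields the curation rules inspect:
measurement type, relation, value, activity flags, target confidence,
target relationship type, organism and molecular weight. `filterRecords()`
retains records with

* molecular weight below 1000 Da,
* a direct target relationship (`"D"`) with a human target at the highest
  confidence level (9),
* an exact (`"="`) Ki, IC50 or Kd measurement,
* no `"inactive"`, `"not active"`, `"inconclusive"` or
  `"potential transcription error"` flag.

Potencies are converted to negative decadic logarithms of the molar value
(`toPPotency()`: 100 nM becomes 7.0) and compounds weaker than 10 µM
(p-potency < 5.0) are removed. When a compound-target pair has several
measurements they are averaged on the log scale before thresholding — the
common ChEMBL curation convention; cases straddling the threshold are
reported in the log, since the choice is consequential there and upstream
databases are not explicit about it. Potential assay-interference compounds
are removed with a pluggable substructure catalog
(`defaultInterferenceCatalog()`); the shipped file is a small set of
reactive chemotypes (quinones, rhodanines, azo dyes, acyl halides) rather
than any complete published filter set, and users with real data should
substitute their preferred catalog.

`assignClasses()` then defines, per target pair, DT compounds (curated
activity against both targets) and ST compounds (curated activity against
exactly one target and *no recorded activity of any quality* against the
partner). A compound whose partner-target record exists but did not survive
curation — for example a sub-threshold potency — is excluded rather than
demoted to ST, because calling it single-target would plant known
dual-actives in the negative class. Family-level "related target"
exclusions are supported through an explicit id list (`related_targets`);
ontology lookups are out of scope.

# Molecular representation

Compounds are encoded as binary vectors of layered circular atom
environments: for every atom and every bond radius 0, 1, 2, the
environment is summarized by an iterated neighborhood signature
(`enumerateEnvironments()`). The radius-0 invariant is (element, heavy
degree, implicit hydrogen count, formal charge, ring membership) — the
standard Morgan atom invariants — and each iteration appends the sorted
(bond order, neighbor signature) list, so identifiers are independent of
atom numbering. Environments with an identical atom/bond cover within one
molecule collapse to a single feature, the usual ECFP deduplication, which
keeps atom-level feature counting meaningful. On a reference set of
molecules the resulting unique-environment counts equal those of the
standard RDKit Morgan implementation (radius 2), which the test suite
pins down.

Two deliberate choices:

* **Identifiers are canonical strings, not hashed integers.** The analysis
  requires that no two environments share a vector position; mapping the
  full signature string through a dictionary (`buildVocabulary()`) makes
  collisions impossible by construction instead of improbable. Positions
  are assigned in sorted identifier order, so a vocabulary depends only on
  the set of environments observed, not on compound order.
* **Vocabularies are built from training compounds only** (per trial), so
  that no information about test compounds leaks into the representation.
  Environments of a test compound that were never seen in training are
  dropped and counted — the same mechanism carries one pair's model onto
  the other pair's compounds in cross-prediction. A `vocab_scope = "all"`
  switch exists for diagnostic use.

Chirality is ignored in the invariants, and no physicochemical descriptors
are added: the point of the analysis is structural interpretability.
`mapFeatureToAtoms()` inverts the representation, returning every
occurrence (atom and bond cover) of a feature in a compound.

# Balanced random forest

The DT class is outnumbered by STs by roughly 1:50, so plain bootstrap
forests would learn the prior. In the BRF (`trainBRF()`), every tree draws
an exactly class-balanced sample: the minority class with replacement at
its own size, the majority class under-sampled without replacement to the
same size (`balancedBootstrap()`). Trees are CART with Gini impurity;
features are binary, so thresholds sit at 0.5. Each node records its
balanced-sample coverage, and each leaf's value is the DT fraction of the
compounds reaching it; the ensemble probability is the mean over trees.
These coverages and leaf fractions are exactly the quantities the Shapley
explainer conditions on, which is why the forest is implemented in the
package rather than delegated to a generic library that does not expose
them. At each split, `mtry = sqrt(p)` randomly chosen features are
inspected (the random-forest default; the search continues past `mtry`
features only if none yields a valid split); split ties break to the
smallest vector position so that training is fully reproducible from the
seed.

Hyperparameters (number of trees 25–400, minimum samples to split 2–10,
minimum leaf size 1–10, `brfDefaultGrid()`) can be selected by stratified
10-fold cross-validation within the training set; the selection metric is
MCC, the stricter of the two reported measures under class imbalance, with
ties broken by BA and then model size. The synthetic system is separable
enough that the grid search is inert there, so the desk-scale defaults use
a single grid point (100 trees, split 2, leaf 1) and skip the internal CV;
the full grid remains available for real data.

Accuracy is reported as balanced accuracy `BA = (TPR + TNR)/2` and the
Matthews correlation coefficient, with `MCC = 0` whenever a denominator
factor vanishes (degenerate predictors). Evaluation uses repeated trials
(`runTrials()`, default 10): per trial a stratified 50/50 train/test split
— an even split keeps enough DT compounds on the test side to make the
confusion matrix meaningful at these class sizes — followed by vocabulary construction,
training and held-out evaluation. `crossPredict()` applies one pair's
per-trial models to the other pair's compounds; accurate native prediction
together with chance-level cross prediction is the signature that the
learned features are pair-specific rather than generic.

# Exact Shapley values for the forest

For a compound `x`, the SV of feature `i` is its average marginal
contribution to the predicted DT probability over all feature coalitions.
Two implementations exist side by side:

* `shapBruteForce()` evaluates the defining sum directly. The value of a
  coalition is computed by descending each tree, following `x` for
  features in the coalition and averaging the children by training
  coverage otherwise; permutation weights use exact integer factorials.
  This is exponential and refuses more than 15 features — it exists purely
  as an oracle.
* `explainCompounds()` implements the path-dependent polynomial-time
  algorithm for tree ensembles (the EXTEND/UNWIND recursion over decision
  paths, C++ backend), which computes the same conditional-expectation
  game exactly. The test suite drives 200 randomized small ensembles —
  including trees that reuse a feature along one path, the case the path
  bookkeeping exists for — and requires agreement with the oracle below
  1e-9.

The base value is the coverage-weighted mean of leaf values averaged over
trees (`baseValue()`). Because every tree is trained on an exactly
balanced sample, the leaf fractions aggregate to 1/2 in every tree, so a
BRF's base value is 0.5 to floating-point accuracy — the natural anchor
for a probability decomposition. Efficiency
(`base + sum(sv) = prediction`) is asserted at run time for every
explanation the pipeline produces, not only in tests; SVs are reported in
probability units, and features never used by any tree have SV exactly 0
(dummy axiom) and are stored as structural zeros.

A compound's explanation covers the *entire* vocabulary: absent features
receive attributions too, and `partitionSV()` splits each explanation into
present and absent sums. The characteristic pattern of this analysis is
that correct DT predictions are carried by present features while correct
ST predictions are carried by the absence of those same features.

# From attributions to signatures

SVs are local; turning them into a global statement uses rank statistics
rather than thresholds, because attribution magnitudes vary from compound
to compound. `extractPrioritized()` takes, per correctly predicted DT
compound, the `N` present features with the largest positive SV (`N = 5`
by default, roughly 10% of a typical per-compound feature count; ties
break to the smaller position, compounds with fewer than `N` qualifying
features contribute all of them), pools them, and keeps the `M = 10`
features occurring most often (ties by total SV, then position). Only
positive-SV features are eligible: a feature with negative SV cannot be
said to determine a correct DT prediction. Both training and test
compounds of a trial enter the pool by default, matching how the scheme is
meant to summarize a model rather than a split; extraction is per trial,
and recurrent features across trials indicate stability.

Prioritized features are then examined structurally:

* `countPrioritized()` reports how many prioritized features each compound
  contains.
* `colorAtoms()` counts, per atom, the prioritized features whose cover
  includes it (a feature counts once per atom even when it occurs at
  several centers), yielding the familiar substructure heat coloring and
  the induced covered substructure.
* `partitionContributions()` splits a compound's present-feature SVs into
  those mapping entirely inside a designated motif substructure versus
  elsewhere, plus the absent sum — the cumulative decomposition showing
  whether a motif carries the prediction. The motif query is an explicit
  substructure (SMILES) supplied by the user or taken from the generator's
  planted motifs; deriving a maximum common substructure automatically was
  considered and rejected as a separate research problem.
* `absenceSignature()` is the control in the opposite direction: among
  correctly predicted ST compounds, the absent features with the most
  negative SVs are extracted by the same N/M scheme and mapped onto DT
  compounds. Substantial overlap with the presence-based set confirms that
  one motif's presence/absence drives both classes.
* `motifPrevalence()` reports motif match counts per class and within the
  correctly predicted subsets; `motifRecovery()` quantifies, per
  motif-bearing compound, the fraction of motif atoms covered by
  prioritized features.

# The synthetic study system

`syntheticConfig()`/`generateLibrary()` build two target pairs sharing one
pseudo-target (`T_MAOB` with `T_A2AR`, and `T_MAOB` with `T_ACHE`). The
defaults are the study conditions: 60 DT compounds per pair versus 1500 ST
compounds per target (3000 per pair), a motif planting rate of 0.5 and an
ST contamination rate of 0.02 — the regime typical of a curated extract in
which one dominant motif accounts for about half of the DT class while
appearing in only a few percent of STs. Per pair:

* **DT carriers** attach a variable aliphatic tail at one fixed ring
  position of the pair's primary motif (pair 1: caffeine; pair 2:
  coumarin). Because the tail varies only at the attachment point, every
  environment centred more than two bonds away is identical across
  carriers, giving the model a stable class-specific feature block — the
  synthetic analog of a recurring pharmacophore.
* **DT non-carriers** use a pair-specific secondary motif
  (benzothiazinone; cinnamamide) with the same construction, so that the
  DT class — like real dual-target classes — carries a second, less
  frequent signature rather than a single uniform chemotype.
* **ST compounds** decorate one of ~24 common ring scaffolds with 1–3
  random fragments. The fragment pool deliberately includes carbonyl
  fragments, ring-carbonyl scaffolds and phenyl/benzyl substituents so
  that no *generic* chemical property — "has a carbonyl", "has a plain
  benzo ring" — separates the classes; only the specific planted motifs
  do. A 16% fraction of decoys is built on the purine ring, so a
  caffeine-related ring occurs in the ST class in unrelated contexts.
  A 2% contamination fraction is built exactly like motif carriers but
  annotated against a single target, emulating untested dual-actives;
  these become the model's characteristic false positives.
* **Activity values** are sampled log-uniformly between 1 nM and 5 µM, so
  every clean record survives the 10 µM cut; potencies carry no class
  signal by design, keeping the classification purely structural.
* **Dirty records** (3% of rows by default) each violate exactly one
  curation rule, cycling uniformly through the six rule types, with a
  ground-truth sidecar. The 3% default keeps curated class sizes within
  10% of their targets while still exercising every rule; ground-truth
  labels are recomputed after injection (a DT compound losing one record
  to a trap becomes "excluded", exactly what the curation rules should
  produce).

Compound assembly works at the SMILES level: fragments are inserted as
single-bond branches at hydrogen-bearing, non-bracket ring-atom tokens,
and every generated SMILES is round-trip validated through the parser.
Molecules average ~20–30 heavy atoms and ~20–30 unique environments —
smaller than typical curated drug-like compound sets, which is why the
default `N = 5` corresponds to a larger fraction of a compound's features
here than it would on real data.

# What the synthetic tests do and do not show

The end-to-end tests establish that, under the default conditions, the
implementation recovers planted ground truth: native BA above 0.9 with
cross-prediction at chance, correct DT predictions dominated by
present-feature SV sums and correct ST predictions by absent sums, and
prioritized feature sets that cover at least 80% of the planted motif's
atoms in at least 90% of motif-bearing correctly predicted DT compounds
while sharing no feature between the two pairs. These are statements about
the *method* — curation fidelity, representation invertibility, exactness
of the attribution, and the extraction scheme's ability to concentrate on
a real signal. They are not statements about real bioactivity data: real
DT classes are structurally heterogeneous beyond two motifs, assay noise
correlates with potency, and data incompleteness is not independent of
chemistry. On real extracts the same pipeline applies unchanged, but
accuracy and signature coherence are empirical outcomes, not guarantees.

# Numerical and reproducibility choices

* All randomness derives from explicit integer seeds; child seeds for
  trials, bootstraps and fold assignments are derived arithmetically and
  kept below 2^31. Reruns of a pipeline are bit-identical, which the test
  suite checks via manifest hashes.
* The efficiency identity is enforced at 1e-9 at run time; explainer vs
  oracle agreement is tested at 1e-9; the BRF base value is tested at
  1e-12 against 0.5.
* Tie-breaks (split selection, top-N, top-M) are deterministic and
  documented at each site.
* Degenerate inputs: single-class training data, pairs without DT
  compounds, empty post-filter tables, compounds without attachment
  points, unparseable SMILES and zero-coverage trees all raise or warn
  explicitly rather than propagating silently.
* Desk-scale problem sizes: the default synthetic study (two pairs, ~3000
  compounds per pair, 10 trials of 100 trees) runs end to end in a few
  minutes on one CPU; explanations for all ~3000 compounds of a trial take
  seconds through the C++ explainer.

# Known limitations

* SMILES parsing, canonicalization and aromaticity perception follow
  OpenBabel (via ChemmineR); molecules outside its aromaticity model may
  featurize differently than under other toolkits, although renumbering
  invariance always holds.
* Substructure matching uses element- and bond-order-labelled subgraph
  monomorphism; SMARTS expressiveness (beyond the interference catalog,
  which does use OpenBabel SMARTS) is not supported in motif queries —
  motif queries are plain molecules.
* The brute-force oracle is capped at 15 features by design.
* Salt stripping, stereochemistry-aware deduplication and live database
  access are out of scope; the ingestion contract is a documented CSV.
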