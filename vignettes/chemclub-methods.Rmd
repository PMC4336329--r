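---
title: "Chemical-club analysis and ensemble hERG classification: methods"
author: "chemclub authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chemical-club analysis and ensemble hERG classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Unintended blockade of the hERG potassium channel delays cardiac
repolarization (long QT syndrome) and is a leading cause of drug
withdrawals, so chemical libraries are screened for hERG inhibition early.
In a large, diverse library, most measured compounds are inactive and the
active ~5% are not scattered at random: potent blockers tend to cluster in
a limited number of structural neighbourhoods, while moderate inhibitors
are structurally heterogeneous.  `chemclub` implements the computational
side of such a screen: structure networks over the library, a statistic
that quantifies whether potent compounds are preferentially similar to one
another, an imbalance-corrected ensemble classifier that scores each
compound's hERG risk, and a six-class summary of how predictability and
activity co-locate in chemical space.

## Structure networks

Compounds are nodes; edges join structurally similar pairs.  The primary
(2D) criterion is the Tanimoto coefficient between fingerprint bit sets,

$$TC_{i,j} = \frac{|F_i \cap F_j|}{|F_i \cup F_j|},$$

with an edge when $TC > 0.7$ — a conventional similarity cutoff, applied
strictly.  All pairs are compared exactly (blocked matrix products, no
approximate bucketing), so the network equals a brute-force scan by
construction.  Two further criteria are supported: imported edge lists
(e.g. precomputed 3D conformer-overlap neighbours), merged with the 2D
network by edge-set union over a shared node universe, and a Murcko
scaffold hierarchy in which scaffolds are connected by single-ring
addition/removal.

Two empty fingerprints have an undefined Tanimoto ratio; we define it as 0
(with a warning) rather than 1, so featureless records never create
spurious edges.

### Scaffold hierarchy details

The Murcko framework keeps ring systems and the linkers between them:
terminal atoms are pruned iteratively (ring atoms always survive), and
atoms joined to the remaining framework by a double or triple bond are
then re-attached, so exocyclic carbonyls travel with their ring or linker
while side chains that merely end in a double bond are removed.  For the
hierarchy, every ring of a scaffold is tried for removal (exhaustive
enumeration, not one canonical path): a ring is removable iff deleting the
atoms exclusive to it leaves a single connected component; the remnant is
re-pruned and canonicalized, and duplicate children collapse.  The scaffold
set of a library is closed under this operation down to single rings;
intermediate scaffolds realised by no compound are kept as *virtual* nodes
and flagged, since the club statistic on the scaffold level is computed on
realised scaffolds only.  A scaffold's activity is the best (maximum)
inhibition among its member compounds — a deliberate choice (the
alternative, e.g. mean-member, dilutes a potent scaffold decorated with
many inactive variants).

## The chemical-club coefficient

Classical rich-club analysis thresholds nodes by degree; here nodes are
thresholded by activity.  With $N_t$ the number of compounds whose percent
inhibition strictly exceeds $t$ and $E_t$ the edges among them,

$$ChC_t = \frac{2E_t}{N_t\,(N_t-1)} \in [0, 1],$$

the fraction of realised similarity links among all possible ones.  For
$N_t < 2$ the value is reported as absent (`NA`), not 0, distinguishing
"no club members" from "members with no edges".

The null model permutes the activity annotations over the fixed network
(`n_perm = 1000` by default) and reports, per threshold, the null mean and
standard deviation and the one-sided empirical p-value with the add-one
estimator $p = (1 + r)/(1 + n_{perm})$, where $r$ counts permutations with
$ChC \ge ChC_{obs}$ (compared on integer edge counts, avoiding float
ties).  The estimator never returns 0; its minimum at 1000 permutations is
$1/1001 < 0.001$.  One-sided $\ge$ is the relevant direction: the question
is whether potent compounds are *more* densely connected than chance.
Per-permutation work is $O(E)$ (threshold counts via `findInterval` on
edge-endpoint minima), so 1000 permutations on a $10^5$-edge network take
seconds.

If the $N_t$ club members split into the maximal number of discrete
similar pairs (2-cliques), $E_t = N_t/2$ and $ChC_t = 1/(N_t - 1)$.
Observed values below this two-clique bound imply singletons among the
club members; the bound therefore caps the number of structural
communities compatible with an observed coefficient.

The default threshold grid is integer percent steps from the 1st to the
99th percentile of the observed activities — the figure-ready range; the
grid is fully configurable and all club quantities are defined per
threshold, so the choice only affects resolution.

## Ensemble classification

Activity is binarized at the conventional potency cutoff: *blocker* iff
inhibition at 10 µM is strictly greater than 50%.  The boundary value 50
goes to the nonblocker class, since blockers are defined by the strict
inequality.

A naive library is heavily imbalanced (~5% blockers), so each classifier
is trained on *balanced batches*: all training-set blockers plus an
equally sized random draw of nonblockers, repeated
$\lfloor NB/B \rfloor$ times so that each batch sees a different
nonblocker sample and (almost) every nonblocker is used.  Under 5-fold
cross-validation every compound receives one vote per batch per classifier
family from models that never saw it:

* **hBS** (hERG Blocker Score): the mean blocker vote over all models of
  both families, in $[0,1]$.
* **PS** (Predictability Score): the fraction of votes matching the true
  label — identically $hBS$ for blockers and $1 - hBS$ for nonblockers.

PS is discretized with closed boundaries (predictable $PS \ge 0.95$,
unpredictable $PS \le 0.05$, else inconsistent), while hBS histogram bins
use strict boundaries (high $> 0.95$, low $< 0.05$).  The asymmetry is
deliberate: the two conventions are kept exactly as each quantity is
defined.  Per-family P/I/U classes are intersected — P (or U) only when
both families agree, everything else I — and crossed with the activity
label into the six classes P-B … U-NB.

### Base learners

*Winnow2*: a multiplicative-update online linear classifier over sparse
binary features — fingerprint bits plus quantile-binned physicochemical
descriptors (logP, max basic pKa, min acidic pKa, Wiener index; 10 bins
fit on the training folds only, a dedicated "absent" bin for undefined
pKa).  Weights start at 1; prediction is blocker iff the active-weight sum
strictly exceeds $\theta$ (default: half the feature-space size); false
negatives multiply active weights by $\alpha = 2$, false positives divide.
The exact parametrization of the historical implementation is not public;
this canonical variant is used and all three hyperparameters are exposed.
Descriptor values are inputs (columns of the compound table) rather than
computed, except the Wiener index, which is computed from structure when
SMILES are present.

*RBF-kernel classifier*: a soft-margin SVM on the 1024-bit fingerprint
(served by `e1071::svm`; the package owns the interface, CV protocol and
determinism contract).  Cost and width are grid-searched ($C \in 2^{-5}
\ldots 2^{15}$, $\gamma \in 2^{-15} \ldots 2^{3}$, powers of 4) by 5-fold
CV balanced accuracy on the *first balanced batch of fold 1*, then frozen
for every batch — one optimisation reused across the ensemble, mirroring
the practice of holding kernel parameters constant across balanced
batches.  Ties resolve to the first grid member, so the search is
deterministic under its seed.

All sampling is hierarchically seeded (master seed → fold seed → per-batch
seeds), so a run is reproducible end to end and hBS does not depend on the
order in which batches are trained.

### External libraries

For an unseen collection, the ensemble is retrained on the full reference
library (no folds), external compounds duplicated in the reference (by id
or identical structure) are excluded and reported, and a compound is a
predicted blocker iff its pooled hBS strictly exceeds 0.9 — a deliberately
conservative cutoff for prioritisation.  Compounds are summarised per
384-well plate: predicted blocker counts, per-plate recall when
measurements exist (absent, not 0/0, for plates without observed
blockers), the least-squares $R^2$ of predicted on observed counts, and
the Spearman rank correlation of the plate ranking.

## Summary network

Within-group connection density is $cd_G = E/(V(V-1))$ — implemented *as
defined*, although it is half the usual undirected density and reaches
only 1/2 on a complete group; a `convention = "undirected"` switch
($2E/(V(V-1))$) is provided.  Between-group density is $E/(V_1 V_2)$.
Because figure edge widths encode *relative* density, a max-normalized
column accompanies the raw values.

Each hBS level pairs one blocker with one nonblocker class (consistent
votes: P-B/U-NB; intermediate: I-B/I-NB; low: U-B/P-NB), and enrichment
compares the class's share of its level with the library-wide base rate,
e.g.

$$E_{P\text{-}B} = \frac{P_B/(P_B+U_{NB})}{B/(B+NB)}.$$

Under label-randomized data all six enrichments concentrate at 1; values
far above 1 for P-B mark the high-risk, structurally self-similar blocker
space.

## The synthetic library generator

No public generative model of a real diversity library exists, so all
distributional choices here are explicit stand-ins with the statistical
features the analysis relies on:

* **Cluster structure.** Each of 20 (default) clusters owns a random
  marker-bit template of 200 bits out of 1024.  Potent clusters (potency
  mean 85%) keep their template intact; moderate clusters (means 5–35%)
  retain each template bit with probability 0.7 per compound, making weak
  inhibitors structurally heterogeneous.  Every compound adds 8 random
  background bits, then each of the 1024 bits flips with probability 0.02.
  The marker density is deliberately higher than real circular-fingerprint
  densities: with 2% bit noise on 1024 bits (~20 random flips), ~200
  shared markers keep within-cluster Tanimoto near 0.79 — above the 0.7
  edge threshold — whereas realistic ~50-bit fingerprints would lose all
  edges.  The generator trades fingerprint realism for a faithful network
  topology.
* **Activities.** 10 µM inhibition is Normal(cluster mean, sd 8),
  truncated (by inverse-CDF, no boundary atoms) to $[-20, 100]$ — screens
  report small negative inhibitions.  The blocker fraction defaults to 5%;
  moderate cluster means are capped at 35 so their upper tails do not
  inflate it.  1 µM inhibition is a Beta(5, 2) shrinkage of the 10 µM
  value (reflected for negative values), enforcing concentration
  monotonicity; no claim of mechanistic realism is made.
* **QC metadata.** Per-well tail current, seal resistance and drop rate
  are drawn from a passing mixture, with a 4% minority drawn from failing
  modes — echoing the high pass rates of production screens.  The QC
  filter retains wells with tail current > 0.2 nA, seal > 30 MOhm and
  drop < 25%, all strict.
* **Descriptors.** logP is shifted +1.5 in potent clusters (blockers are
  lipophilic), pKa columns are present for only part of the library
  (exercising the "absent" descriptor bin), and the Wiener column is
  log-normal.
* **External libraries** reuse a configurable fraction of the reference
  cluster templates (potent clusters first), partition compounds into
  384-well plates, and draw per-plate cluster mixtures from a
  Dirichlet(0.5), so plate-level blocker counts genuinely vary.

A *null* library keeps the structural clusters but jointly permutes the
two inhibition columns, factorizing (fingerprint, activity) exactly — the
calibration target for the permutation test.

**What passing tests do and do not show.**  The generator reproduces the
statistical skeleton (cluster-concentrated potency, class imbalance,
plate heterogeneity, QC failures) but not real chemistry: no synthesizable
structures, no activity cliffs within a series, no assay artefacts beyond
the QC fields, and cluster separation is cleaner than real chemotype
boundaries.  Tests passing on these libraries certify the algorithms and
their contracts, not field performance on a real screen.

## Numerical choices and degenerate inputs

* Strict inequalities throughout (`TC > 0.7`, activity `> t`, blocker
  `> 50`, QC thresholds, hBS bins) — as each quantity is defined.
* Ties in the Winnow decision (score = θ) go to nonblocker; ties in the
  grid search go to the first grid member.
* `ChC` with $N_t < 2$, recall on blocker-free plates, degree–activity
  correlation under zero variance, and enrichments of an empty hBS level
  are *absent* (`NA`) with a reason, never silently 0.
* Empty-fingerprint pairs score 0 similarity with a warning.
* Permutation p-values compare integer edge counts, not floats.
* All randomness passes through one master seed; derived seeds stay below
  $2^{31}$.

## Problem sizes used in the shipped checks

The test suite exercises the pipeline at reduced scale, chosen as the
smallest sizes at which the targeted properties are stable: permutation
calibration on 200 structure-free replicates of $n = 500$ compounds
(199 permutations each, KS test against uniform, with the club placed at
a threshold where it holds many compounds and edges so the edge-count
statistic is effectively continuous — tiny clubs tie the add-one
estimator at $p = 1$ by construction); power on a planted
library of $n = 2{,}000$ with 1000 permutations; classifier recovery on
$n = 5{,}000$ with 5% blockers and 2% bit noise, plus a fully overlapping
external collection of 8 plates.  The statistics themselves scale linearly
in edges (club profile) and in models × compounds (ensemble), and the
package has been run on $10^4$-compound libraries without special
handling.

## Known limitations

* Functional-class (pharmacophoric) atom typing is not available in the
  OpenBabel toolkit backing `compute_fingerprint()`; the `"fcfp6"` kind is
  served by the radius-3 circular fingerprint with standard atom
  invariants.  Synthetic-library analyses are unaffected (fingerprints are
  generated directly as bit sets).
* 3D conformer-overlap similarity is consumed only as imported edge lists;
  the package does not compute conformer ensembles.
* The scaffold-removal rule (delete atoms exclusive to a ring; reject
  disconnected remnants) is one defensible reading of ring-based scaffold
  hierarchies; other tools prune differently in fused corner cases.  The
  rule is fixture-locked in the tests.
* The ensemble classifies; it does not regress continuous inhibition, and
  hBS is a vote share, not a calibrated probability.
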