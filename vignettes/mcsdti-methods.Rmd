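---
title: "Two classification strategies for drug-target interaction prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two classification strategies for drug-target interaction prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcsdti)
```

## The problem: within-class imbalance across targets

Chemogenomic drug-target interaction (DTI) data come as a binary matrix
$Y \in \{0,1\}^{u \times v}$ over $u$ drugs and $v$ protein targets, with
companion drug fingerprints $D \in \{0,1\}^{u \times p}$, protein
descriptors $T \in \mathbb{R}^{v \times q}$, and similarity matrices
$S_d$, $S_t$. Two structural facts dominate these data. First, they are
very sparse: the public benchmark families range from about 6.4% density
on the smallest set down to 0.064% on the largest. Second, the known
interactions concentrate heavily on a minority of targets — on the order
of half or more of all interactions sit on the top 20% of targets. So a
handful of targets have plenty of positive examples, while most targets
have one or two, or none.

No single classifier handles both regimes well. A per-target classifier
starves on the sparse targets; pooling a target with its neighbours floods
a well-annotated target with its neighbours' negatives. The method
implemented here therefore splits the targets by a degree threshold
$\tau$ and treats the two sides differently, and — just as importantly —
*evaluates* the two sides independently, because any pooled metric is
dominated by the heavily annotated targets and hides whatever happens on
the sparse ones.

## The two strategies

**Partition.** A target with more than $\tau$ known interactions belongs
to TWLNI ("targets with larger numbers of interactions"); otherwise to
TWSNI. The `<=` boundary on the small side was chosen so that $\tau = 1$
makes TWSNI exactly the degree-$\le 1$ targets, the regime the
similarity-transfer strategy is intended for. By default the counts are
taken on the full matrix — the split is a preprocessing decision, fixed
before cross-validation; `partition_per_fold = TRUE` recomputes it from
each training submatrix for users who prefer to treat the degree itself
as unseen. Conventional settings for $\tau$ are 1, 3 and 5; with larger
$\tau$ the per-target trees get more positives per target and improve,
while the transfer side degrades, so $\tau = 1$ is the sensible setting
when the sparse part is what matters.

**TWLNI: one CART tree per target.** For target $t_j$, the drug feature
rows are the samples and column $Y_{\cdot j}$ is the label; nothing from
any other column enters training (`run_twlni_fold`). Trees suit this
high-dimensional small-sample setting because a greedy impurity split is
driven by the number of *useful* features, not the total dimension. The
hyperparameters follow the common decision-tree defaults in DTI work
(Gini impurity, minimum parent size 10, minimum leaf size 1, no pruning,
`tree_control()`); the ranking score of a test drug is the positive
fraction of the leaf it reaches, the natural continuous score for a
classification tree evaluated by AUC. A target whose training column is
single-class is *unfittable*; it is skipped and reported rather than
imputed. Evaluation is macro-averaged: one AUC per target over its test
drugs, then the mean over targets with a defined AUC.

**TWSNI: nearest-profile transfer.** The sparse targets borrow from their
single most similar neighbour:
$$\hat Y(:, t_{new}) = S_t(t_{new}, t^*)\, Y(:, t^*), \qquad
  \hat Y(d_{new}, :) = S_d(d_{new}, d^*)\, Y(d^*, :),$$
with the pair score the mean of the two sides. Only the *nearest*
neighbour is used: similarity measures over drugs and proteins are
imperfect, and the further a profile is, the less its similarity value
can be trusted, so averaging in remoter profiles (as the weighted-profile
baseline does) trades robustness for noise. All targets serve as transfer
sources — the whole point is to reach information the sparse targets do
not have — but only the TWSNI part is ever evaluated, by one pooled AUC
over all (test drug, TWSNI target) pairs. Pooling is forced by the
arithmetic: at $\tau = 1$ most TWSNI targets have at most one positive,
so per-target AUCs are mostly undefined.

One term in the target-side rule is unobservable under drug-wise
cross-validation: $Y(d_{new}, t^*)$ is a test-drug label. We substitute
the drug-side estimate $S_d(d_{new}, d^*) Y(d^*, t^*)$, which stays
strictly inside the two transfer rules and provably touches no test
label (the test suite flips all test labels and asserts bit-identical
scores). This chaining is one reasonable reading of an underdetermined
step; the alternative — treating the term as 0 — collapses the target
side entirely for test drugs.

## Cold-start cross-validation and evaluation

Folds partition the *drugs* (`make_drug_folds`, balanced, seeded), so a
test drug has no observed interactions at training time for any method —
the new-drug, cold-start setting. Inside `run_mcsdti` the test rows of
$Y$ are additionally zeroed before any scorer runs, as a structural
guarantee rather than a promise. Per fold, the TWLNI part yields a
macro-AUC and the TWSNI part a pooled AUC; each part is aggregated over
folds as mean and sample (n−1) standard deviation and reported as
`mean ± sd`. The two parts are never combined into one number.

AUC uses the Mann-Whitney formulation with midrank tie handling —
$(\#\{pos > neg\} + \tfrac12\#\{ties\}) / (n_+ n_-)$ — and the package
carries a literal double-loop oracle (`auc_oracle`) against which the
rank-based implementation is verified to $10^{-12}$ on a thousand random
tie-heavy instances. Undefined AUCs (single-class) are typed results, not
numbers; targets with single-class test labels are excluded from the
macro mean and listed.

## Comparison methods

Four classical baselines run under the identical folds and the identical
two-part evaluators (`run_baseline_cv`): a single global CART tree on
concatenated $[d \| t]$ pair vectors (dimension $p + q$, 2461 at the
conventional 1024-bit fingerprint and 1437-descriptor defaults); nearest
profile over the full pair space; weighted profile (the
similarity-normalized average over *all* candidates, which reduces to
nearest profile when the similarity row is one-hot); and network-based
inference, two-pass degree-normalized resource diffusion on the training
bipartite graph. NBI deserves a caveat this package makes explicit:
being similarity-free, it has no way to score a cold-start drug — a test
drug has no training edges, so its diffusion profile is empty and its
scores are 0 (with a warning). Ensemble and kernel-regression
comparison methods whose formulations live in their own papers are
deliberately not included.

## The synthetic data generator

Real benchmark data cannot ship with a package; the generator
(`generator_config`, `generate_dataset`) reproduces exactly the
statistical structure the method's behaviour depends on, and nothing
else:

* **Sparsity.** Interaction count `round(u*v*density)`; the default
  density 0.064 mirrors the densest (and smallest) public benchmark so
  the whole suite runs quickly.
* **Degree skew.** Per-target degrees are a largest-remainder
  apportionment over Zipf weights $j^{-skew}$, permuted over targets.
  Apportionment rather than a multinomial draw makes conservation and
  the uniform limit exact, not merely expected. At the default
  `skew = 1`, the top 20% of targets carry at least half the
  interactions, matching the documented concentration.
* **Plantable signal.** Each target owns a hidden set of
  `round(signal*p)` fingerprint bits; an interacting drug carries its
  target's full signature, every bit otherwise appears at a background
  rate of 0.1, and labels are then flipped with probability `noise`.
  The flip probability is deliberately the *only* corruption of the
  feature-to-label rule: at `noise = 0` the planted signal is exact and
  a tree can recover it, at `signal = 0` held-out performance is chance,
  and the degradation in between is controlled by one dial.
* **Similarities** are derived from the features themselves (Tanimoto
  over fingerprints, Gaussian kernel with the median heuristic over
  descriptors), so the drug similarity really does reflect shared target
  signatures.

What the generator does *not* emulate: real substructure correlation
between chemically related drugs, homology structure among proteins,
dataset-specific bit marginals, or biased negative sampling (every
unobserved pair is a true negative here, which is optimistic). Passing
the recovery tests therefore demonstrates that the pipeline's mechanics
are sound — signal in, ranking out, no leakage — not that any particular
AUC level will be attained on real chemogenomic data.

## Numerical and design choices

* Tie-breaking in nearest-neighbour selection is lexicographic on the
  identifier — deterministic and order-independent.
* Fold sizes differ by at most one; all randomness (folds, generator)
  flows through explicit integer seeds via scoped RNG, never global
  state left behind.
* Degenerate inputs are typed, not silent: single-class training columns
  (`mcsdti_unfittable`), undefined AUCs, empty TWLNI sets, all-zero
  similarity rows, and cold-start NBI rows each produce a typed result
  or warning.
* Reports serialize to JSON at full double precision (17 significant
  digits), so a written report re-reads numerically identical.
* Test-suite problem sizes: unit tests run on 30-drug/12-target
  configurations with 64 fingerprint bits; the recovery and
  strategy-crossover experiments run 20 seeds at the full default
  configuration (54 x 26, p = 1024, q = 1437), five folds each.

## Known limitations

* The partition is degree-based only; adaptive or multi-way splits are
  out of scope.
* Nearest-profile transfer is sensitive to the single nearest neighbour
  by construction; on data where the similarity measure is locally
  miscalibrated the TWSNI part can underperform broader averages. If the
  sparse part is critical, cross-validate the choice on training data
  first.
* AUC is the only metric; the report schema leaves room for others but
  none are computed.
* With `noise > 0` the realized density drifts upward from the request
  (flips hit far more negatives than positives); the density guarantee
  applies at small noise.
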