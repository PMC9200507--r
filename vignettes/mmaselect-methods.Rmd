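---
title: "Memory-based attribute selection for clinical risk tables: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Memory-based attribute selection for clinical risk tables: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmaselect)
```

## The problem

Chronic-disease screening tables — the UCI heart disease, PIMA diabetes,
breast cancer and hepatitis files are the canonical examples — mix numeric
and categorical attributes, carry missing cells, and include attributes that
are redundant or pure noise. With $k$ attributes there are $2^k$ candidate
subsets, so exhaustive wrapper selection is infeasible beyond small $k$.
`mmaselect` implements a hybrid procedure for this setting:

1. **Preprocessing** — mean/mode imputation, then min-max normalization
   $p' = (p - \min_p)/(\max_p - \min_p)$ so every numeric attribute lies in
   $[0, 1]$.
2. **Memory-based metaheuristic attribute selection (MMAS)** — a tabu-style
   local search over feature subsets with a fixed-capacity FIFO memory
   buffer (the *metalist*) of visited subsets.
3. **K-means outlier filtering** — Lloyd's algorithm with Euclidean
   distance and $k = 2$ clusters; records far from their cluster are
   removed.
4. **Naive Bayes classification** under stratified 10-fold
   cross-validation, scored by accuracy, precision, recall, F-score,
   Matthews correlation coefficient (MCC), and latency (train + test time).

## The search

A subset is a bit mask over the feature columns. The walk starts from a
random subset (each bit Bernoulli(1/2), rerolled if empty), then repeatedly
evaluates all Hamming-distance-1 neighbors and moves to the best admissible
one — *even when it is worse than the current subset*, which is what lets
the walk leave local optima. Admissibility is governed by the memory
buffer: a neighbor stored in the buffer is skipped unless it would beat the
global best (aspiration). The chosen subset is pushed into the buffer,
which evicts strictly first-in-first-out once its capacity (the *tenure*,
default 10) is full. If every neighbor is tabu and none aspirates, the walk
is forced to the neighbor with the oldest buffer entry. The search stops at
`max_iter` (default 100), after `stall_limit` (default 20) iterations
without improving the global best, or on reaching an optional
`fitness_threshold`. Ties break towards higher fitness, then smaller
subsets, then the lexicographically smallest mask, making every run fully
deterministic given its seed.

### The fitness function

The fitness of subset $S$ is

$$f(S) = \overline{\mathrm{acc}}_{\mathrm{CV}}(S) -
         \lambda \, |S| / d,$$

the mean stratified inner-cross-validation accuracy (default 5 folds) of
the Naive Bayes classifier restricted to $S$, minus a small parsimony
penalty. The default $\lambda = 0.01$ lets accuracy dominate and only
breaks near-ties towards smaller subsets; $\lambda = 0$ gives a pure
wrapper. The inner folds are fixed once per search context (by the config
seed), so fitness is a deterministic function of the mask and is memoized —
every selector sharing a context sees the identical, cached value for the
same subset. The functional form is this package's design choice: it is
the natural wrapper objective for a pipeline whose downstream classifier is
Naive Bayes and whose stated goal is dropping low-relevance attributes.

### Relevance scores

Per-attribute relevance on a 0–10 scale is the selection frequency across
independent restarts: `relevance_scores()` runs `restarts` single-restart
searches (consecutive seeds, hence different inner folds per restart, which
is deliberate — a feature must survive fold resampling to score highly) and
multiplies the selection frequency by 10. Features below `drop_threshold`
(default 3) are flagged low-relevance.

### Baselines

Greedy forward stepwise, best-first search, a canonical genetic algorithm
(tournament size 2, uniform crossover 0.6, bit-flip mutation $1/d$,
elitism 1, population 20, 50 generations) and binary PSO
($w = 0.7$, $c_1 = c_2 = 1.5$, velocities clamped to $[-6, 6]$, sigmoid
transfer) all optimize the *same* memoized fitness, so comparisons isolate
the search strategy. The parameter values are fixed textbook defaults,
chosen for reproducibility rather than as reconstructions of any specific
legacy toolkit. An exhaustive oracle (`exhaustive_select()`, guarded to
$d \le 20$) provides ground truth on small problems.

## Clustering and outlier removal

`fit_kmeans()` is Lloyd's iteration with Forgy initialization ($k$ distinct
rows drawn by seed; k-means++ behind a flag), nearest-centroid assignment
with ties to the lowest cluster index, and empty-cluster repair at the row
farthest from its centroid. The per-iteration within-cluster
sum of squares is recorded, and is non-increasing by construction.
Categorical attributes are one-hot encoded before clustering
(`encode_features()`), since Euclidean distance assumes real vectors;
Naive Bayes instead consumes categoricals directly.

A record is an outlier when its distance to its assigned centroid exceeds
the cluster's mean distance plus `z_cut` (default 3) standard deviations of
the within-cluster distances. Two robustness rules matter in practice:

* **Small-cluster rule.** With extreme records present, the
  inertia-optimal $k = 2$ fit often isolates them into a tiny cluster of
  their own, where they would trivially "comply". Clusters holding fewer
  than `min_cluster_frac` (default 5%) of the rows are therefore treated as
  non-representative and their members are scored against the nearest
  representative cluster.
* **Drop cap.** At most `max_drop_frac` (default 10%) of the rows are ever
  removed; if more are flagged, only the most extreme are dropped, with a
  warning.

Whether this filtering step should remove *records* or *attributes* is
genuinely ambiguous in the wider literature on combined
clustering-plus-selection pipelines; both readings are shipped. The default
(`outlier_axis = "rows"`) removes records, which is what a distance
threshold naturally measures; `"columns"` drops features whose encoded
columns have point-biserial correlation below a threshold with the
2-cluster assignment.

Note that exact-recovery guarantees for planted outliers are only
well-posed on *compact* clusters: Gaussian data has unbounded tails, so at
$z = 3$ a genuine tail record is occasionally and correctly flagged. The
validation suite therefore checks exact recovery on uniform-ball clusters,
whose distance support is bounded strictly inside the threshold.

## Naive Bayes

A mixed Gaussian/categorical classifier: per class, numeric features get
maximum-likelihood mean and variance (floored at `var_floor = 1e-9`, scaled
for min-max-normalized inputs, so constant columns never divide by zero);
categorical features get Laplace-smoothed level frequencies
$(n_{c\ell} + \alpha)/(n_c + \alpha L)$ with $\alpha = 1$. Posteriors are
evaluated in log space and normalized, so thousand-feature rows neither
underflow nor overflow; an unseen level receives the smoothing mass
$\alpha/(n_c + \alpha L)$, never zero. Prediction ties go to the class
with the larger prior, then the lower class index. The classifier runs on
normalized attributes because the pipeline is sequential — the same
representation feeds selection, clustering and classification.

## Evaluation protocol

Stratified 10-fold cross-validation: each class is shuffled by seed and
dealt round-robin (with a random fold offset), so per-class counts differ
by at most one across folds and the folds exactly partition the rows.
Stratification is the default because clinical screening tables are
typically class-imbalanced and per-fold accuracy averages are otherwise
high-variance; an unstratified mode is available. Metrics are computed on
the confusion counts pooled over all held-out predictions (a per-fold-mean
reading is possible but pooling is the default); any metric with a zero
denominator is reported as 0 with a warning. The F-score is computed as
$2\mathrm{TP}/(2\mathrm{TP}+\mathrm{FP}+\mathrm{FN})$, algebraically the
harmonic mean $2PR/(P+R)$ — `f_score_from_pr()` exposes the identity,
which the acceptance suite verifies against the published benchmark
metrics shipped in `inst/extdata/`. Latency (train + test seconds) is
reported but never asserted, being hardware-dependent.

The full-table min-max normalizer is fitted *before* cross-validation by
default, matching the sequential pipeline design; `refit_per_fold = TRUE`
gives the leakage-free variant. The same caveat applies more strongly to
selection: `run_pipeline()` selects features on the full table and then
cross-validates, so on pure-noise data the selection stage leaks label
noise into the evaluation and inflates mean CV accuracy by a few points —
the familiar selection-outside-CV bias. The package's null-calibration
checks therefore ablate the selection stage (`use_mmas = FALSE`), which is
exactly the configuration whose expected accuracy is the majority-class
rate.

The two stage orders (selection before clustering, or clustering first)
are both defensible and both available via `pipeline_config(order = )`;
the default runs selection first.

## The synthetic generator

`generate_synthetic()` emulates a clinical screening table with known
ground truth: informative numeric features are $N(\pm\delta/2, 1)$ by
class; informative categoricals use three levels with mirrored class-biased
odds (level logits $\pm\delta/4$ on the outer levels); redundant features
are affine copies of informative ones plus $N(0, 0.05)$ noise — detectable
redundancy without exact collinearity; noise features are class-independent.
Defaults (768 rows, 3 informative at $\delta = 1.5$, 5 noise, balanced
classes) mirror a mid-sized screening table such as the 768-record PIMA
file. The Bayes-optimal accuracy of the numeric-Gaussian part is available
in closed form from the Mahalanobis separation $\Delta = \delta\sqrt{F}$
and the class prior $\pi_1$:
$\pi_1\Phi(\Delta/2 - c) + (1-\pi_1)\Phi(\Delta/2 + c)$ with
$c = \log((1-\pi_1)/\pi_1)/\Delta$, reducing to $\Phi(\Delta/2)$ for
balanced classes.

What the generator does *not* emulate: realistic marginal distributions of
specific clinical attributes, correlated noise, longitudinal structure, or
missingness that depends on the outcome. Passing the planted-truth suites
shows the machinery is correct and well-calibrated under the generative
assumptions; it does not certify performance on any particular real
dataset.

## Problem sizes used in validation

The validation and acceptance suites use deliberately moderate problem
sizes, chosen so each check is sharp for its purpose: oracle-equivalence
runs use $d = 10$ features and $n = 150$ rows over 20 seeds (the
exhaustive oracle evaluates all $2^{10}-1$ subsets); planted-feature
recovery uses $n = 500$ with 3 informative against 7 noise features and 20
relevance restarts; null and single-signal calibration use $n = 2000$ and
$n = 5000$, where the 99% binomial intervals are tight enough to be
informative; outlier recovery uses 200-row compact two-ball tables with 3
planted records at 100 times the data radius, over 20 seeds.

## Known limitations

* The wrapper fitness is a cross-validated estimate; with small $n$ its
  noise exceeds the parsimony penalty, so near-duplicate subsets can tie
  and chance-correlated noise features can enter the selection. The
  relevance scores' restart averaging is the mitigation.
* Binary classes only; multi-class labels are out of scope.
* K-means outlier filtering assumes roughly convex, comparably scaled
  clusters — hence the mandatory normalization upstream.
* With `outlier_axis = "columns"` the correlation threshold is a heuristic
  with no planted-truth guarantee; it is shipped for completeness.
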