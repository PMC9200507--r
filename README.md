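# mmaselect

Wrapper attribute selection for tabular clinical risk data, built around a
**memory-based metaheuristic attribute selector (MMAS)**: a tabu-style local
search over feature subsets that keeps a fixed-capacity FIFO buffer (the
*metalist*) of visited subsets, combined with **K-means outlier filtering**
and a mixed Gaussian/categorical **Naive Bayes** classifier evaluated by
stratified 10-fold cross-validation.

## Who this is for

Analysts working with chronic-disease screening tables (heart disease,
diabetes, breast cancer, hepatitis and the like): mixed numeric/categorical
attributes, missing cells, a binary outcome, and more attributes than are
actually informative. With $k$ attributes there are $2^k$ candidate
subsets; `mmaselect` searches that space with a memory-buffered
neighborhood walk instead of enumerating it, and reports which attributes
matter on a 0–10 relevance scale.

## The method in brief

A feature subset $S$ is scored by the wrapper fitness

$$f(S) = \overline{\mathrm{acc}}_{\mathrm{CV}}(S) - \lambda\,|S|/d,$$

the mean stratified inner-CV Naive Bayes accuracy on the columns of $S$
minus a small parsimony penalty ($\lambda = 0.01$ by default). The search
walks the Hamming-1 neighborhood of the current subset, moving to the best
admissible neighbor even when it is worse than the current one; subsets in
the FIFO memory buffer are inadmissible unless they would beat the global
best (aspiration). The pipeline then removes records that fail a
$z$-score distance test against their K-means cluster, and evaluates the
result with stratified 10-fold cross-validation: accuracy, precision,
recall, F-score, MCC and latency. Greedy stepwise, best-first, genetic and
binary-PSO baselines share the identical memoized fitness, and an
exhaustive oracle provides ground truth for $d \le 20$.

## Worked example

```r
library(mmaselect)

# a synthetic screening table with known ground truth:
# 3 informative features (class separation 1.5 sd) hidden among 7 noise
g   <- generate_synthetic(synthetic_spec(n_rows = 500, n_informative = 3,
                                         n_noise = 7, effect_size = 1.5,
                                         seed = 42))
rep <- run_pipeline(g$table, pipeline_config(seed = 7))
print(rep)
#> <pipeline_report> 500 rows x 10 features -> 499 rows x 3 features
#>   selected: inf_01, inf_02, inf_03
#>   outlier rows dropped: 1
#> <cv_result> 10-fold, mean accuracy 0.9197 (folds 0.820-1.000)
#>   precision 0.9221, recall 0.9064, F 0.9142, MCC 0.8391; latency 0.011s

relevance_scores(g$table, search_config(seed = 7, restarts = 10))
#> <relevance_scores> attribute ranking on a 0-10 scale:
#>   inf_01                10.0
#>   inf_02                10.0
#>   inf_03                10.0
#>   noi_03                 2.0  (low relevance)
#>   noi_05                 2.0  (low relevance)
#>   ...
```

The selector recovered exactly the three planted informative attributes
(every noise attribute scores below the relevance drop threshold of 3),
one record was removed as a cluster outlier, and the cross-validated
accuracy of the reduced model, 0.92, sits close to the closed-form
Bayes-optimal rate for this generator setting
(`g$bayes_accuracy` = Φ(1.5·√3/2) ≈ 0.903 — the CV estimate includes the
mild optimism of selecting on the full table; see the methods vignette).

Real CSV/TSV files enter through `read_table()` (last column is the class
by default, `"?"`/empty cells are missing), followed by
`impute_missing()`; `run_compare()` produces the method-by-method
comparison table.

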