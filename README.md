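# linkclust

Record linkage — deciding which records in one or several tabular data
sources refer to the same real-world individual — is a core step in health
informatics and epidemiology: a patient's history is scattered across
agencies that share no universal identifier, and values are polluted by
typing errors and near-homophones.  `linkclust` implements a deterministic
linkage pipeline built around **complete-linkage hierarchical clustering**,
which bounds the diameter of every output cluster and thereby avoids the
*chaining problem* of single-linkage approaches (records `sweat` — `sheat` —
`heat` chain into one cluster at edit threshold 1 even though the ends are 2
apart; complete linkage never merges all three).

## The method

Given datasets `D_1 … D_m` (possibly with different attribute sets), a
threshold τ, blocking and comparison attribute lists and a priority list:

1. **Exact matching.** For every pair of datasets whose attribute sets are
   in a subset relation (self-pairs included), records are serialised over
   the common attributes, radix-sorted, and runs of equal keys are merged;
   merges accumulate across pairs by union-find.  Each of the resulting `N′`
   clusters of identical records contributes one representative (the member
   with the most attributes).
2. **Blocking.** Each representative's blocking-attribute value of length
   `l` is indexed under its `l − k + 1` k-mers; with an alphabet of size
   `s` there are at most `s^k` blocks.  Only pairs sharing a block are ever
   compared.
3. **Threshold graph / single linkage.**  An edge joins two representatives
   whose record distance — the sum over shared comparison attributes of a
   banded, threshold-bounded Levenshtein distance (reversal and truncation
   variants available) — is at most τ.  Connected components of this graph
   are the single-linkage clusters.
4. **Complete linkage.**  Inside each component, clusters grow from
   singletons by repeatedly merging the pair at minimum complete-linkage
   (furthest-pair) distance while that minimum is ≤ τ, i.e. the dendrogram
   cut at height τ: `d(A, B) = max {d(a, b) : a ∈ A, b ∈ B}`.  Every output
   cluster has diameter ≤ τ.
5. **Priority refinement and expansion.**  Records whose assignment was
   ambiguous move to the cluster that best matches a user-ranked priority
   attribute list (rank `i` of `m` weighs `2^(m−i)`), never breaking the
   diameter bound; representatives are then expanded back to their exact
   clusters, yielding a partition of the whole corpus.

A deterministic parallel executor partitions each phase (prefix ranges for
sorting, squared-size-balanced block groups for edge construction,
component shards for linkage) and is guaranteed — and tested — to produce a
byte-identical cluster file for every worker count.

Quality is scored against a ground-truth attribute with four cluster
categories — Type I (perfect), Type II (pure but incomplete), Type III
(complete but impure), Type IV (fragments of several individuals) — and a
majority-owner accuracy: each cluster is owned by the individual holding
most of its records, and accuracy is the fraction of records belonging to
their cluster's owner.

## Worked example

Five records across two sources (`A`: Cade Bale / Cade Bolt / Thor Glenn,
`B`: Thor Glenn / Cade Balt), blocking on 3-mers of the first name,
comparison on first + last name, threshold 1, date of birth as priority:

```r
library(linkclust)
fx <- worked_example_fixture()
res <- record_link(fx$datasets, fx$config)
res
#> <rl_linkage>
#>   n_datasets         2
#>   n_records          5
#>   n_exact_clusters   4
#>   n_blocks           4
#>   n_candidate_pairs  3
#>   n_edges            2
#>   n_components       2
#>   n_final_clusters   3
res$clustering$assignments[, .(cluster_id, dataset_id, row_index)]
#>    cluster_id dataset_id row_index
#> 1:          1          A         0
#> 2:          1          B         1
#> 3:          2          A         1
#> 4:          3          A         2
#> 5:          3          B         0
```

The two identical Thor Glenn records collapse in the exact phase (5 → 4
representatives).  The three Cade records form one single-linkage component;
complete linkage refuses to merge Bale with Bolt (distance 2 > 1), and the
date-of-birth priority resolves the Balt tie towards Bale — cluster 1 is
`{Bale (A,0), Balt (B,1)}`, Bolt stays alone, the Thors form cluster 3.

On synthetic data (1,000 individuals × 10 copies, 15 % single-edit
corruption, threshold 2):

```r
sim <- generate_type1(1000, seed = 42)
cfg <- link_config("first_name", comparison = c("first_name", "last_name"),
                   threshold = 2, priority = "dob", truth = "ssn")
out <- record_link(sim$datasets, cfg)
evaluate_clustering(out$clustering, sim$truth)
#> <rl_evaluation> 10000 records in 1000 cluster(s)
#>   Type I        10000 records  (100.00%)
#>   Type II           0 records  (  0.00%)
#>   Type III          0 records  (  0.00%)
#>   Type IV           0 records  (  0.00%)
#>   correct labels: 10000 / 10000  (accuracy 1.0000)
```

## Command line

A thin wrapper lives at `system.file("cli", "linkclust.R", package = "linkclust")`:

```sh
Rscript linkclust.R simulate --type 1 --n 1000 --copies 10 --p 0.15 --seed 42 --out simdir
Rscript linkclust.R link --config link.cfg --data simdir/copy01.csv --data simdir/copy02.csv --out clusters.csv
Rscript linkclust.R evaluate --clusters clusters.csv --truth simdir/truth.csv --out report.txt
```

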