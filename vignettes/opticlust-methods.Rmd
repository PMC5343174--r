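---
title: "Metric-optimized OTU clustering: model, conventions, and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metric-optimized OTU clustering: model, conventions, and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opticlustr)
```

## The model

Given pairwise dissimilarities between unique amplicon sequences and a cutoff
$c$ (default 0.03), every unordered pair is *close* ($d \le c$; the boundary
is inclusive) or *far*. A partition of the sequences into OTUs induces a
confusion matrix over all $n(n-1)/2$ pairs: TP = close pairs co-clustered,
FN = close pairs split, FP = far pairs co-clustered, TN = far pairs split.
Clustering quality is the Matthews correlation coefficient,

$$\mathrm{MCC} = \frac{TP \cdot TN - FP \cdot FN}
  {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}},$$

the correlation between the observed co-clustering relation and the ideal
close/far relation. The optimizer performs local search on partitions: each
iteration interrogates every sequence in a seeded random order and commits,
immediately, the best-scoring placement among (i) its current OTU, (ii) every
OTU containing at least one of its close neighbors, and (iii) a new singleton
OTU.

Only the close-pair adjacency is retained after reading a distance file. The
distances themselves never enter the objective, so memory scales with the
number of close pairs rather than with all pairs.

### Why candidate OTUs can be restricted to close-neighbor OTUs

Moving a sequence into an OTU that contains none of its close neighbors
changes the confusion matrix, relative to the new-OTU option, by converting
TNs into FPs only (it adds $m$ far co-clustered pairs and no close ones).
Every maximize-direction metric in the registry is non-increasing in FP at
fixed TP, and every minimize-direction metric is non-decreasing in FP, so
such a move can never strictly beat opening a new OTU. Restricting the
candidate set is therefore lossless while making the cost of one
interrogation proportional to the sequence's close-neighbor count.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `cutoff` | 0.03 | inclusive close/far threshold on dissimilarity (fraction) |
| `metric` | `"mcc"` | optimization target; 14 registered metrics, each with a fixed direction |
| `seed_mode` | `"singletons"` | initial partition: one OTU per sequence, or all in one OTU |
| `delta` | `1e-4` | stop when the per-iteration metric change is `< delta`; `0` = full convergence (stop when exactly unchanged) |
| `max_iterations` | 100 | hard cap on iterations |
| `shuffle_seed` | 1 | seed of the interrogation order (one shuffle per run, reused across iterations) |

The `delta` and `max_iterations` defaults follow the established defaults for
this algorithm family; full convergence (`delta = 0`) is the more
conservative setting and is what the test suite and the acceptance script
use. Replicate runs (`opti_cluster_reps`) derive shuffle seeds
deterministically as `seed, seed + 1, ...` so a whole stability experiment is
reproducible from one integer; `stability_report` summarizes the replicates
by the percent coefficient of variation, $100 \cdot s/\bar{x}$ with the
sample ($n-1$) standard deviation.

## Conventions for degenerate confusion matrices

The MCC denominator vanishes whenever a marginal is empty. The package fixes:

* `FP = 0` and `FN = 0` — the partition makes no pair-level errors — scores
  **1**, even when the denominator is zero. This covers, e.g., an
  all-singleton partition of a graph with no close pairs.
* any other zero marginal scores **0**.
* ratio metrics with an empty denominator return the optimum under their
  direction (sensitivity with `TP + FN = 0` returns 1, FDR with
  `TP + FP = 0` returns 0, and so on), so degenerate seedings are not
  artificially penalized.

Exact metric ties are broken deterministically: the current OTU is preferred,
then the new-OTU option, then candidate OTUs enumerated by decreasing size
with ties by lexicographically smallest member. Together with the seeded
shuffle, identical inputs and configuration reproduce bit-identical results.
Confusion counts are maintained in double precision (exact integer arithmetic
up to $2^{53}$), and the MCC denominator is computed as a product of square
roots so the four-way product cannot overflow for any realistic pair count.

Optimizing FP, specificity, PPV, or TN from singleton seeding leaves every
sequence in its own OTU: the seeding is already optimal for those one-sided
targets and ties prefer the current OTU. This degeneracy is reproduced
deliberately, not prevented; it is why a metric balancing all four cells is
the default.

## Stopping behavior

With `delta > 0` the run stops the first time an iteration improves the
metric by less than `delta` ("partial convergence"); with `delta = 0` it
stops when the metric is exactly unchanged. Because the candidate set always
contains the current placement, committed moves never worsen the metric, and
the per-iteration trace (recorded in the fitted object, iteration 0 = the
seeding state) is monotone in the metric's direction. On the package's noisy
planted benchmark partial convergence typically saves one or more iterations
relative to full convergence at a negligible metric difference; the
acceptance script reports both iteration counts.

## The cluster-splitting heuristic

`split_cluster` groups sequences by their taxonomic label at a chosen rank,
clusters each taxon independently, merges the per-taxon OTU lists, and
evaluates the merged partition against the *full* close-pair graph. A close
pair whose members are classified into different taxa can never be
co-clustered, so each such pair is a forced false negative, the merged MCC is
bounded by the plain-clustering optimum, and the merged partition tends to
contain more OTUs. Taxonomy is consumed as a `name<TAB>lineage` table
(bootstrap confidences in parentheses are stripped; classification and
confidence filtering happen upstream). Sequences unclassified at the split
rank are grouped under their deepest classified label as an
`<label>_unclassified` pseudo-taxon. Per-taxon shuffle seeds are derived from
the master seed plus a stable polynomial hash of the taxon label, so the
merged result does not depend on the order taxa are processed in.

## What the synthetic generators emulate

`simulate_planted` draws within-cluster distances uniformly from
`[0.005, 0.03]` and between-cluster distances from `[0.05, 0.25]` — tight
clusters well separated from the background, with every within-cluster pair
at or below the cutoff. The noise model flips each pair's close/far status
independently with probability `noise_rate` by redrawing its distance from
the opposite range, the simplest emulation of sequencing error pushing pairs
across the threshold. `simulate_abundance` reproduces only the abundance
structure of standard synthetic benchmark communities: an even profile (every
sequence at 100 reads) or a staggered profile (counts uniform on 1–200);
abundances are reporting metadata and never affect clustering, which operates
on unique sequences. `simulate_taxonomy` assigns whole truth clusters to
genus lineages and misassigns individual sequences with probability
`cross_rate`, emulating the misclassification that makes cluster splitting
lossy.

Real amplicon data differ in ways these fixtures deliberately ignore:
distances are not drawn independently per pair (they satisfy metric-like
constraints), clusters are not uniformly tight, close-pair density varies by
lineage, and error-inflated sequences form near-threshold halos around
abundant templates. Passing the planted tests therefore demonstrates
correctness of the machinery — parsing, counting, incremental updates,
convergence, splitting bookkeeping — not that any particular MCC level will
be attained on real communities.

## Problem sizes used by the test suite

The suite cross-checks the implementation against independent oracles at
desk scale: exhaustive enumeration of all 877 set partitions on 7-sequence
graphs (100 random instances, best of 10 shuffled runs), brute-force
all-pairs confusion counts up to $n = 50$ (500 instances), full recomputation
of the confusion matrix after every committed move up to $n = 100$ (100
instances), and planted-partition recovery with 35 clusters of sizes 1–10
(200 sequences, 10 replicate shuffles). These sizes were chosen so each
oracle remains exact and the whole suite runs in minutes.

## Known limitations

* **Graphs with no far pairs.** If every pair is close (possible for a small
  taxon sub-problem after splitting), every non-perfect partition scores an
  MCC of 0 under the zero-marginal convention, so singleton-seeded search has
  no gradient and legitimately stays at singletons; one-OTU seeding starts at
  the perfect single OTU. Such degenerate sub-problems are rare in practice
  (they require a taxon with no internal structure) but are the reason
  single-taxon splitting fixtures in the tests always contain at least two
  truth clusters per taxon.
* **One-OTU seeding can trap whole clusters.** From the all-in-one seed, the
  first member of an intact tight cluster to leave sacrifices all its
  within-cluster TPs at once; for clusters above a size threshold (roughly
  degree 6 at the benchmark's densities) this strictly decreases the MCC, and
  since all the sequence's neighbors are still inside the remnant OTU there
  is no other candidate. The resulting remnant-plus-pure-OTUs state is a
  strict local optimum of single-sequence moves. Singleton seeding does not
  have this failure mode and is the default; the acceptance script reports
  the one-OTU result on the planted benchmark so the gap is visible rather
  than hidden.
* **Local optima behind metric valleys.** Single-sequence hill climbing
  cannot cross configurations that require two coordinated moves (e.g.
  completing two imperfect triangles simultaneously); on a small fraction of
  random graphs the global optimum is a fixed point of the move rules yet
  unreachable from singleton seeding under any shuffle order. Repeating the
  clustering with several seeds and keeping the best result is the practical
  mitigation, and is what `opti_cluster_reps` automates.
* **Scale.** The implementation is pure R and is intended for method
  development and desk-scale validation, not for clustering millions of
  unique sequences.
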