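---
title: "Boolean implication networks: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boolean implication networks: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boolimpl)
```

## The model

`boolimpl` analyzes a genes × samples expression matrix on log2 scale. The
underlying assumption is that many genes are effectively *switch-like*: the
samples split into a low-expression regime and a high-expression regime,
and the informative structure is which regime each sample occupies, not the
exact value. Three layers build on that assumption.

**Discretization.** A gene's sorted values are fitted with a single rising
step: for every split point $k$ the two segment means are the fitted
values, and the $k$ minimizing the residual sum of squares wins. The fit
quality is

$$F = \frac{\sum_i (\hat X_i - \bar X)^2 / (m-1)}{\sum_i (X_i - \hat X_i)^2 / (n-m)},$$

and the threshold $t$ is the midpoint of the two segment means. Values in
$t \pm 0.5$ — a 2-fold band on log2 scale — are *intermediate*: they are
too close to the switch point to call, and are ignored in all pairwise
statistics. Genes whose calls are nearly one-sided (fewer than 5% low or
5% high over all samples) are removed before network construction: a gene
with no real dynamic range cannot be told "all low" from "all high", so
its threshold is an artifact of noise.

**Pairwise implications.** For a gene pair, the doubly non-intermediate
samples populate four quadrants $a_{00}, a_{01}, a_{10}, a_{11}$ (first
index: gene A low/high; second: gene B). Under independence the expected
count of quadrant $ij$ is $\hat n = (\text{rowsum} \cdot
\text{colsum})/\text{total}$, and sparsity is declared when

$$S = \frac{\hat n - n}{\sqrt{\hat n}} > s_{thr}
\quad\text{and}\quad
p = \frac{1}{2}\left(\frac{n}{\text{rowsum}} + \frac{n}{\text{colsum}}\right) < p_{thr}.$$

$S$ measures how far below expectation the quadrant sits (in units of the
Poisson scale $\sqrt{\hat n}$) and $p$ is an error rate — the average of
the two conditional probabilities of landing in the forbidden quadrant. A
single sparse quadrant yields the corresponding asymmetric implication
(e.g. empty $a_{00}$ means "A low ⇒ B high"); the sparse diagonal pairs
$\{a_{01}, a_{10}\}$ and $\{a_{00}, a_{11}\}$ yield *equivalent* and
*opposite*. Any other sparse pattern (adjacent pair, three or more) can
only arise from degenerate marginals and is classified as no relation.

**Clusters and signatures.** Equivalent genes are redundant; clustering
them compresses the network. Equivalence edges are weighted by the Jaccard
similarity of the two genes' closed equivalence neighborhoods and edges
below 0.5 are dropped — two genes stay connected only if they share at
least half of their combined partners — and the connected components of
the remainder are the clusters. Cluster-to-cluster edges are typed by the
majority relationship between one cluster's best-connected gene and up to
six rank-sampled representatives of the other. Finally, signatures score
samples with a modified Z-score centered at the switch point,
$z = (x - t - 0.5)/(3\sigma)$, averaged within gene sets and combined with
+1/−1 weights.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `margin` | 0.5 (log2 units) | half-width of the intermediate band; 0.5 = 2-fold |
| `min_frac` | 0.05 | minimum fraction of low and of high calls per gene |
| `sthr` | 3 | sparsity statistic threshold (≈3 Poisson sd below expectation) |
| `pthr` | 0.1 | maximum conditional error rate of a sparse quadrant |
| `jaccard_cutoff` | 0.5 | minimum neighborhood sharing for an equivalence edge |
| `majority_threshold` | 0.5 | strict majority required to type a cluster edge |
| `auc_up`, `auc_down` | 0.6, 0.3 | single-gene ROC-AUC filters (all training cohorts) |
| `cluster_auc` | 0.6 | cluster-score AUC required for candidacy |
| `top_k` | 20 | signature genes kept per direction |

The statistical defaults (`sthr`, `pthr`, `margin`, `min_frac`, the AUC
filters and `top_k`) are the framework's standard operating point and are
deliberately not tuned per dataset; every run records the resolved
configuration in its manifest.

## Numerical and design choices

* **Degrees of freedom.** The F statistic uses $m = 3$ (two segment means
  plus the breakpoint); `m_df` is an argument for users who prefer a
  different accounting. $F$ is reported as `Inf` for a perfect step rather
  than failing on the zero denominator.
* **Ties and determinism.** SSE ties across split points go to the
  smallest $k$; rank ties within clusters break lexicographically by gene
  id; cluster ids order by decreasing size then smallest member. The whole
  pipeline is deterministic given the input and seed, and independent of
  gene input order.
* **Degenerate pairs.** A quadrant whose expectation or marginal is zero
  gets a not-sparse sentinel ($S = -\infty$, $p = 1$) instead of an
  error — such genes are effectively one-sided after pairing and should
  already have been caught by the 5% filter. Pairs with no doubly
  non-intermediate sample classify as no relation.
* **Quadrant statistics beyond $a_{00}$.** The expectation/error-rate
  construction is applied to each quadrant with its own row and column
  marginals (the low/low case generalized symmetrically).
* **Boundary values.** Values exactly at $t \pm 0.5$ are intermediate, so
  small numeric perturbations at the band edge can only move calls into
  the excluded class, never across it.
* **Jaccard pruning scope.** Pruning applies to *all* equivalence edges by
  default; a variant that computes a minimum spanning tree per component
  (weight $1-J$) and prunes only tree edges is available as
  `mode = "mst"`. On clean planted cliques both modes agree; the all-edges
  rule is simpler and is the default.
* **"Overwhelming majority."** Operationalized as a strict majority
  (> 0.5) of all tested representative pairs, with absent relations
  counting in the denominator — absence is evidence against a
  cluster-level edge. The winning share is reported as `support` so users
  can apply stricter cutoffs post hoc.
* **Normalization sign.** The composite normalization is read as
  $(x - t - 0.5)/(3\sigma)$, anchoring zero at the upper edge of the noise
  band. The alternative reading $(x - (t - 0.5))/(3\sigma)$ differs only
  by a constant $1/(3\sigma)$ per gene and cannot change sample rankings
  or AUCs.
* **Dataset-local Boolean quantities.** Thresholds and standard deviations
  are recomputed on every evaluation dataset rather than carried over from
  training: the discretization is a property of a cohort, not of a gene.
  A consequence worth knowing: under a per-gene affine rescaling of a
  dataset, composite scores shift by a sample-independent constant (the
  fixed 0.5 margin does not rescale), so rankings and AUCs are invariant
  but raw score values are not.
* **Down-gene orientation.** Single-gene AUCs always use the "higher
  expression = case" orientation, so down-regulated genes are selected by
  AUC < 0.3 rather than being flipped first.
* **Cluster candidacy.** The published procedure selects signature
  clusters "based on how strongly they predict" the disease state; here
  that is operationalized as a cluster-score AUC cutoff (0.6) in all
  training cohorts, with an explicit cluster-id override for curated
  choices. Singleton clusters are excluded from candidacy by default
  (`min_cluster_size = 2`).
* **Duplicate gene ids** on input collapse to the per-sample mean by
  default (order-independent); a max-variance-row policy is available.
  Missing values are rejected outright rather than imputed.

## What the synthetic data emulates — and what it does not

The generator produces Gaussian-mixture bimodal genes over latent binary
states (default modes 2 and 5 at sd 0.5, i.e. 6 sd of separation; per-gene
high fractions uniform in [0.2, 0.8]), implication structure by
constraining child states given parent states, equivalence cliques by
sharing a latent state, and case/control effects by tying planted genes'
states to the class label with a 3-sd shift across cohorts of 100 samples
per class — the scale of a typical bulk RNA-seq disease cohort. This is
the world the Boolean analysis assumes, which is exactly what makes it the
right test bed for the machinery: planted relations are recovered at known
rates, permutation must destroy them, and training must find exactly the
planted signature.

It does **not** emulate RNA-seq count noise (negative binomial
overdispersion), batch or platform effects, correlated null genes,
partial-penetrance disease effects, or annotation mismatch between
cohorts. Passing tests therefore certify the inference machinery, not
performance on real tissue data; on real data the dynamic-range filter,
the permutation FDR and the cluster-consistency check are the diagnostics
to watch.

Problem sizes in the shipped tests and in `scripts/acceptance.R` (500–
2,000 genes, 150–600 samples, 20 training replicates) were chosen as the
smallest designs at which the planted effects are comfortably identified
by the statistics involved; all of them regenerate in code at run time.

## Known limitations

* Only single-step (one threshold) discretization is implemented; genes
  with three regimes are forced into two.
* Implication calls carry no per-edge multiple-testing correction; error
  control is via the `sthr`/`pthr` operating point plus the permutation
  FDR diagnostic, matching the framework's standard practice.
* `train_signature` assumes binary labels; multi-class staging is out of
  scope.
* Cluster selection for signatures is a pre-filter, not a learned model;
  curated cluster choices must be passed explicitly.
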