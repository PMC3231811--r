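---
title: "Constructing gene regulatory networks from biclustered expression data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing gene regulatory networks from biclustered expression data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bicgrn)
```

## The problem and the approach

Expression compendia measure thousands of genes over at most a few hundred
conditions. Learning one Bayesian network over all genes is statistically
hopeless at that sample size, and gene regulation is context-specific: a
regulatory relationship may hold only under heat shock, or only in a cell-cycle
phase. `bicgrn` therefore works module-by-module:

1. **Preprocess** the matrix (impute missing values, drop uninformative
   genes).
2. **Bicluster**: find subsets of genes coherent over subsets of conditions,
   with four algorithm families of different inductive bias.
3. **Compare biclusterings biologically**: which algorithm's biclusters are
   enriched for annotation terms, and how strongly?
4. **Learn** one discrete Bayesian network per bicluster, using only the
   bicluster's own conditions as samples.
5. **Merge** all subnetwork edges into one directed network.
6. **Evaluate** against a gold-standard interaction network over the full
   ordered-pair universe, including an indirect-edge reclassification, and
   inspect the network's topology.

Each stage reads and writes plain-text formats (expression TSV, bicluster
text, SIF / edge lists, annotation TSV/GAF), so externally produced bicluster
results can be dropped into the comparison and learning stages.

## Preprocessing

*KNN imputation* (`knn_impute`) is gene-wise: the distance between two gene
rows is the Euclidean distance over their mutually observed conditions divided
by the number of shared conditions, and a missing cell is the unweighted mean
of the `k` (default 10) nearest rows observed in that condition. Imputation
never touches observed entries and is idempotent.

*Filtration* (`filter_genes`) removes genes whose observed-value variance
falls below a threshold (default 0, i.e. off — filtering is an explicit
choice) or whose missing fraction exceeds a cap (default 1).

*Discretization* (`discretize_quantile`) bins each gene independently into
`levels` (default 3) equal-frequency states by rank, with ties always assigned
to the lower bin. Equal-frequency binning makes the downstream BDe score
invariant to monotone distortions of each gene's scale, which matters for
log-ratio data of heterogeneous dynamic range. Three states is the
conventional under/base/over-expressed coding; it is a default, not a claim
that any particular historical pipeline used the same cardinality.

## Biclustering algorithms

**Cheng–Church** (`cc_bicluster`) minimises the mean squared residue
$H(I,J) = \frac{1}{|I||J|}\sum_{i,j}(x_{ij}-x_{iJ}-x_{Ij}+x_{IJ})^2$, which is
zero exactly for constant and additive (row effect + column effect)
submatrices. The search is the classical one: multiple node deletion (drop all
rows/columns with mean residue above $\alpha \cdot H$, default
$\alpha = 1.2$), single node deletion until $H \le \delta$ (default
$\delta = 0.5$), then node addition of rows/columns whose residue does not
exceed the current $H$ — an addition batch is kept only when the overall $H$
does not increase, so the $\delta$ certificate from the deletion phase is
never lost. After each bicluster is reported, its cells are overwritten with
uniform random values over the matrix's observed range (seeded), so later
iterations find different structure. Consequence worth knowing: biclusters
after the first carry their $\delta$ guarantee with respect to the *working*
matrix; a later bicluster that overlaps a masked region may exceed $\delta$ on
the original data.

**ISA** (`isa_bicluster`) alternates two thresholded scoring steps from random
gene seeds (default 5 genes per seed): condition scores are means of
*row-standardized* values over the current gene set, gene scores are means of
*column-standardized* values over the kept conditions, both scaled by
$\sqrt{|set|}$ so the thresholds $t_g = t_c = 2$ read as z-scores under the
null. The thresholds are applied **sign-consistently**, and every seed is
iterated twice — once for up-regulated and once for down-regulated modules
(the direction is recorded in the bicluster's `score`). The design point is
deliberate: a magnitude-only rule ($|z| \ge t$) lets the anticorrelated tail
leak in — for a planted up-module the non-module conditions sit near
$z \approx -1.9$ simply because the module inflates its genes' row means, so
about half of them cross a two-sided threshold and drag background genes into
the module. With sign-consistent thresholds a planted 15-gene module
(amplitude four background SDs over 10 of 40 conditions) is recovered
*exactly*. Converged modules are fixed points of the iteration; modules with
gene-set Jaccard ≥ 0.9 are deduplicated (first kept).

**OPSM** (`opsm_bicluster`) looks for rows that are strictly increasing along
a common ordering of a column subset (within-row ties broken by column index,
making the order total and the search deterministic). It grows partial column
orderings level by level, keeping the `l_models = 100` best models per size
(support = number of conforming rows, ties broken lexicographically) and
extending each kept model by inserting an unused column at every position.
Insertion-based growth matters: any in-order *pair* of a planted ordering can
seed the full model, whereas append-only growth must keep one specific prefix
pair alive through every beam cut and loses planted blocks in noise. One
bicluster is reported per model size with at least two supporting rows,
largest support first.

**k-means** (`kmeans_as_biclusters`) is the traditional-clustering baseline:
Lloyd's algorithm on gene rows (Euclidean), 10 seeded replicates keeping the
best within-cluster sum of squares, each non-empty cluster emitted as a
bicluster spanning *all* conditions. Replicates that fail (an empty cluster
under Lloyd) are skipped; the run errors only if every replicate fails.

Default parameters (`cc_params()`, `isa_params()`, `opsm_params()`,
`kmeans_params()`) are the settings conventionally used for the yeast
stress/cell-cycle compendia: $\delta = 0.5$, $\alpha = 1.2$, $M = 100$ for CC;
$t_g = t_c = 2.0$ with 500 seeds for ISA; $l = 100$ for OPSM; 100 clusters,
100 iterations, 10 replicates, Euclidean distance for k-means.

## Enrichment comparison

`enrich_bicluster` tests every term annotating at least one bicluster gene
with the one-sided hypergeometric upper tail
$P(X \ge k)$ for $X \sim \mathrm{Hyper}(N, K, n)$ — the standard test behind
bicluster enrichment tools. The background population is the set of analysed
(post-filter) matrix genes present in the annotation file, not the whole
genome, so the artifact is self-contained. No multiple-testing correction is
applied by default because the comparison methodology sweeps raw significance
levels; `percent_enriched` reports, per algorithm and level $\alpha$, the
percentage of biclusters with at least one term at $p < \alpha$. The filtered
variant additionally requires at least half of a bicluster's genes to carry
any annotation, penalising algorithms whose "enriched" biclusters contain few
annotated genes. `pattern_recovery` reports, per algorithm and target term,
the maximum number of term genes gathered in a single bicluster, flooring
single-gene hits to zero. GO-hierarchy propagation is *not* performed — terms
are used exactly as given in the annotation file.

## Network learning

The BDe family score (`bde_family_score`) is the exact log marginal
likelihood of a child variable given its parents under Dirichlet priors whose
total pseudo-count `ess` (default 1, a neutral prior) is split uniformly over
the $q \times r$ parent-configuration × child-state cells:

$$\sum_j\left[\ln\Gamma(\alpha_j) - \ln\Gamma(\alpha_j+N_j)\right] +
  \sum_{j,k}\left[\ln\Gamma(\alpha_{jk}+N_{jk}) - \ln\Gamma(\alpha_{jk})\right].$$

`greedy_hill_climb` is steepest-ascent from the empty graph over single-edge
additions, deletions and reversals that preserve acyclicity; only strictly
improving moves (score delta > 1e-9, guarding against floating-point cycling)
are taken, with a lexicographic (move type, source, target) tie-break so runs
are bit-reproducible. No restarts are used. On every instance with up to four
nodes that we test, the local optimum coincides with the exhaustive-search
optimum. Note that *increasing* `ess` densifies BDe-optimal structures — on
independent noise an inflated prior will happily add edges — so `ess = 1` is
also the right default for sparse biology.

`sparse_candidate_select` restricts each node's permitted parents to its `c`
highest empirical mutual-information partners (ties by gene ID). Five is the
candidate-set size at which the restricted search comes closest to
unrestricted hill climbing on yeast data; both smaller and larger sets hurt.

`learn_subnetworks` learns one DAG per bicluster on the submatrix of the
bicluster's genes × the bicluster's *own* conditions (discretized
per-gene), so each subnetwork is fitted to the context in which its module is
coherent; k-means clusters simply use all conditions. Biclusters with fewer
than two conditions yield an empty DAG with a warning, and fewer than
`3 × levels` conditions triggers a small-sample warning. `merge_subnetworks`
takes the union of directed edges (each parent contributes parent → child),
drops duplicates and keeps direction — the evaluation universe is directed.

## Evaluation

`confusion_matrix` counts over all ordered pairs $(a,b)$, $a \ne b$, of the
declared gene universe, so TP+FP+TN+FN always equals $N(N-1)$; gold networks
from interaction databases are undirected and are expanded to both
orientations on reading. `auc_from_confusion` interpolates the ROC curve
through $(0,0)$, the single operating point, and $(1,1)$ — hence
$\mathrm{AUROC} = (\mathrm{TPR} + 1 - \mathrm{FPR})/2$ — and the PR curve from
$(0,1)$ through (recall, precision) to $(1,\text{prevalence})$. Text reports
round to 4 decimals, half away from zero.

`modified_reclassify` implements the indirect-interaction argument: database
interactions are often indirect, so a predicted edge $(a,b)$ absent from the
gold network is counted as a true positive when some intermediate gene $c$
has gold interactions $\{a,c\}$ and $\{c,b\}$ — a path of length exactly two
in the undirected gold view; longer paths do not reclassify. Symmetrically,
unpredicted non-gold pairs with a two-hop path move from TN to FN, keeping the
pair universe conserved. On a tiny universe the reclassification can exhaust
all negatives, in which case the modified operating point is undefined and
the modified areas are reported as `NA`. The TN→FN rule is applied exactly as
stated; we make no claim that it is statistically well-calibrated — it is the
published evaluation variant, reproduced faithfully.

`topology_stats` treats edges as undirected and deduplicated: average
neighbour count $2E/N$ over the declared universe, density $2E/(N(N-1))$, and
the diameter of the largest connected component.

## The synthetic study and what the tests do (and do not) show

`simulate_expression` plants blocks in Gaussian background noise: *constant*
blocks add an amplitude shift, *additive* blocks add random row + column
effects drawn from $[-a, a]$, *order-preserving* blocks replace their cells
with values strictly increasing along a hidden column permutation. The default
fixture — 100 genes × 40 conditions, three 15 × 10 modules (one per pattern),
noise SD 1, amplitude 4 — keeps every test fast on one CPU while leaving each
algorithm family a recoverable target matched to its bias: ISA ↔ constant
up-regulation, OPSM ↔ order preservation, CC ↔ additive/constant coherence,
k-means ↔ all-condition clusters. `simulate_bn_data` draws random DAGs (edges
forward along a random node order), CPTs from symmetric Dirichlet(1), and
ancestral samples; `simulate_study` assembles matrix, per-module truth DAGs,
a gold network (both orientations of truth edges plus distractors) and
module-structured annotations.

The generator emulates block structure and missingness but **not** real
microarray pathologies — dye bias, print-tip effects, heavy-tailed noise,
time-series autocorrelation, or the incompleteness and ascertainment bias of
interaction databases. Passing recovery tests therefore demonstrates that the
algorithms and the pipeline are implemented correctly, not that comparable
accuracy would be obtained on biological data, where single-point AUROC values
barely above 0.5 are the realistic outcome.

## Design decisions and numerical choices

* **CC condition identifiability.** For a constant or additive block, the
  submatrix (block genes × *any* condition set) is itself additively coherent
  with the same residue, so no MSR-driven search can localise the block's
  condition set in homogeneous noise; and a block carrying unit noise has
  expected MSR ≈ 0.72 > δ = 0.5, making a high-Jaccard δ-bicluster
  infeasible outright. CC's recovery target is therefore a *dominant*
  constant block (mirroring its documented appetite for very large
  biclusters), scored by gene-set Jaccard; condition recovery is asserted for
  ISA and OPSM, whose scores are signal- rather than coherence-based.
* **ISA sign consistency** (above): two-sided magnitude thresholds provably
  contaminate modules; per-orientation thresholds restore exact recovery.
* **OPSM insertion growth** (above): append-only growth loses planted
  orderings to beam pruning at small model sizes.
* **Hill-climbing tie-breaks** are lexicographic everywhere (moves, candidate
  lists, OPSM models, distance ties in KNN), so every stochastic component is
  bit-reproducible given its seed, and the only randomness is the one the
  seeds control.
* **Degenerate inputs**: genes with no observed values abort imputation by
  name; an all-filtered matrix aborts with advice; single-gene or
  single-condition biclusters learn empty subnetworks with warnings; empty
  bicluster sets report 0% enrichment with a warning.
* **Problem sizes** used by the test-suite and acceptance script (100 × 40
  fixtures, 10-seed end-to-end medians, 50 replicate skeleton recovery,
  2–4-node exhaustive oracles, N ≤ 60 hypergeometric sweeps) were chosen so a
  full run completes in minutes on a single CPU.

## Known limitations

* AUROC/AUPR are computed from a single operating point (the methods produce
  unranked edge sets), so areas compress toward 0.5 and are not comparable
  with ranked-list areas.
* The Cheng–Church δ guarantee for post-first biclusters refers to the masked
  working matrix (see above).
* Biclusters with very few conditions give the BDe learner almost no samples;
  subnetworks from 2–3 condition biclusters are mostly prior.
* No GO DAG propagation, no OBO parsing; annotations are taken as given.
* Only BDe scoring for discrete data is provided; Gaussian scoring and
  regression-based learners are out of scope, as are the biclustering
  algorithms whose results can only be imported (BIMAX, SAMBA, xMotifs, MSBE,
  Bivisu, HCL, cMonkey).
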