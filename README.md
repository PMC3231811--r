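# bicgrn

Gene regulatory network (GRN) construction from microarray expression data by
**biclustering + Bayesian networks**, with a biclustering-comparison toolbox
based on GO-term enrichment.

Genome-wide expression compendia have far more genes than samples, which
cripples whole-matrix network inference. `bicgrn` attacks the dimensionality
problem by first partitioning the expression matrix into biclusters — subsets
of genes with a coherent pattern over a subset of conditions — then learning a
small discrete Bayesian network inside each bicluster, and finally merging the
subnetworks into one directed gene network that is scored against a
gold-standard interaction network. It is aimed at computational biologists who
want to compare biclustering algorithms biologically (which one groups
functionally related genes?) and structurally (which one yields the most
credible network?).

## What it implements

* **Preprocessing** — gene-wise KNN imputation (Euclidean distance over
  mutually observed conditions, scaled by shared-condition count), variance /
  missing-fraction gene filtration, per-gene equal-frequency discretization.
* **Biclustering** — Cheng–Church (`cc_bicluster`; mean squared residue
  `MSR(I,J) = (1/|I||J|) Σ (x_ij − x_iJ − x_Ij + x_IJ)²`, multiple/single node
  deletion to `MSR ≤ δ`, node addition, random masking between iterations);
  the Iterative Signature Algorithm (`isa_bicluster`); order-preserving
  submatrices (`opsm_bicluster`, beam search over partial column orderings);
  k-means gene clusters as all-condition biclusters
  (`kmeans_as_biclusters`); plus import/export of external bicluster results.
* **Enrichment comparison** — one-sided hypergeometric GO-term enrichment per
  bicluster (`enrich_bicluster`), percentage of enriched biclusters per
  significance level with an optional "at least half the genes annotated"
  filtration (`percent_enriched`), and pattern-recovery counting
  (`pattern_recovery`).
* **Network learning** — decomposable log BDe family score
  (`bde_family_score`, Dirichlet prior with equivalent sample size `ess`),
  steepest-ascent hill climbing over single-edge additions / deletions /
  reversals (`greedy_hill_climb`), optional sparse-candidate restriction by
  pairwise mutual information (`sparse_candidate_select`), one subnetwork per
  bicluster (`learn_subnetworks`), duplicate-free edge-union merging
  (`merge_subnetworks`).
* **Evaluation** — confusion matrices over the ordered gene-pair universe
  `N(N−1)` (`confusion_matrix`), single-operating-point ROC/PR areas
  (`auc_from_confusion`, `AUROC = (TPR + 1 − FPR)/2`), the indirect-edge
  reclassification in which a false-positive pair joined by a two-hop
  gold path becomes a true positive (`modified_reclassify`), and topology
  statistics (`topology_stats`).
* **Synthetic fixtures** — seeded generators for expression matrices with
  planted constant / additive / order-preserving biclusters, planted discrete
  Bayesian networks with ancestral samples, gold networks and
  module-structured annotations (`simulate_expression`, `simulate_bn_data`,
  `simulate_study`, ...).
* **Pipeline & CLI** — `run_pipeline()` orchestrates
  impute → filter → bicluster → enrich → learn → merge → evaluate → topology
  and writes networks, comparison/evaluation TSVs and a JSON manifest;
  `inst/cli/bicgrn.R` exposes every stage as a subcommand.

## Worked example

```r
library(bicgrn)

st <- simulate_study(rng_seed = 1)      # planted modules + gold + annotations
m  <- knn_impute(st$matrix)

modules <- isa_bicluster(m, isa_params(t_g = 2, t_c = 2, n_seeds = 100,
                                       rng_seed = 1))
modules
#> BiclusterSet: 21 biclusters (ISA) from a 100 x 40 matrix
bicluster_stats(modules)$gene_coverage
#> [1] 65

head(enrich_bicluster(modules$biclusters[[1]], st$annotations, alpha = 0.01), 3)
#>       term k n  K   N    p_value significant
#> 1    BG_T2 3 5 14 100 0.01884121       FALSE
#> 2 MOD01_T1 2 5 15 100 0.16090619       FALSE
#> 3    BG_T4 2 5 19 100 0.23981218       FALSE

dags <- learn_subnetworks(m, modules)   # one BDe/hill-climbing DAG per module
net  <- merge_subnetworks(dags)
net
#> GeneNetwork: 126 directed edges over 65 genes

modified_reclassify(net, st$gold, union(net$genes, st$gold$genes))
#> EvaluationReport: AUROC 0.5477, AUPR 0.1934 (modified: AUROC 0.5321, AUPR 0.3783)

topology_stats(st$gold)
#> TopologyStats: diameter 9, density 0.031, avg neighbors 3.04 (N=100, E=152)
```

The 21 ISA modules cover 65% of the genes; the first module's strongest term
is a background annotation shared by 3 of its 5 genes (p ≈ 0.019, not
significant at α = 0.01). Learning one Bayesian network per module and merging
gives a 126-edge directed network whose single-point AUROC against the planted
gold standard is 0.5477 — above chance (0.5), and the two-hop
reclassification moves a further share of its false positives to true
positives (modified AUPR 0.38 vs 0.19).

The same run from a shell:

```sh
Rscript inst/cli/bicgrn.R simulate --seed 1 --out demo
Rscript inst/cli/bicgrn.R run --expression demo/expression.tsv \
    --annotations demo/annotations.tsv --gold demo/gold.tsv \
    --gold-directed true --algorithms isa,kmeans --out demo/out --seed 1
```

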