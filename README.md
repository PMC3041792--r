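# gbabias

Tools for measuring, exploiting, and controlling **multifunctionality
(node-degree) bias** in guilt-by-association gene function prediction.

## The problem

Guilt-by-association (GBA) methods predict a gene's function from the
functions of its network neighbours — protein interaction partners,
coexpressed genes, genetic interactors. Cross-validated benchmarks routinely
report strong performance for such methods. A large share of that
performance, however, does not come from *which* gene associates with
*which*: it comes from **multifunctionality** — some genes belong to many
annotation groups, and any method that tends to rank those genes highly is
rewarded across *every* group it is evaluated on.

`gbabias` provides the machinery to quantify and control this effect:

- **Multifunctionality scores.** For gene *g* with universe size *N*,

  ```
  MF(g) = Σ_{groups i : g ∈ i}  1 / (n_in_i × (N − n_in_i))
  ```

  where `n_in_i` is the group's size. Sorting genes by MF gives the single
  fixed ranking that maximizes mean AUROC over all groups — the *optimal
  ranking* — because mean AUROC is linear in rank positions with per-gene
  coefficients equal to the MF weights. A PPV-optimized variant ranks by raw
  annotation count.
- **Node-degree predictors.** Under a prevalence model where gene *i*
  interacts with probability proportional to `p_i · p_j`, the row sums of
  the association matrix (weighted node degrees) recover the ranking of the
  `p_i`. Evaluating the degree ranking as a "predictor" measures how much a
  network's apparent performance needs no association information at all.
- **Individual property networks (IPNs).** The self-outer product of the
  degree vector, thresholded back to the original sparsity (self-pairs
  budgeted, then dropped). An IPN contains no pair-specific information, yet
  can be fed to any network algorithm; its performance is pure bias.
- **Neighbor voting with cross-validation.** Candidates are scored by the
  sum of their association ranks into the training set divided by the sum
  into all non-training genes, with 3-fold CV and AUROC / ROC50 / PPV@k /
  average-precision / CCR evaluation.
- **Degree-preserving nulls.** Double-edge-swap randomization keeps every
  gene's exact degree, giving per-group empirical p-values that answer: is
  this group predicted better than its members' degrees alone explain?
- **Semantic-similarity audits.** Dice/Jaccard annotation overlap of network
  links versus random pairs — a learning-free check that also exposes how
  "functional" an IPN's links look.
- **Synthetic generator.** Annotation matrices with tunable
  multifunctionality skew, `p_i p_j` networks with tunable rank coupling
  `rho` between degree propensity and MF, planted modules with optional
  degree balancing, and latent-factor expression matrices.

## Worked example

```r
library(gbabias)

# Synthetic study conditions: 1000 genes, 100 groups concentrated on
# multifunctional genes, network degrees rank-coupled to MF (rho = 0.9)
cfg <- synth_config(n_genes = 1000, n_groups = 100, min_size = 20,
                    max_size = 100, mf_skew = 2, rho = 0.9,
                    sparsity = 0.04, seed = 7)
annots <- generate_annotations(cfg)
mf  <- multifunctionality_scores(annots)
net <- generate_network(cfg, mf = mf)

nv  <- neighbor_voting(net, annots, folds = 3, seed = 7)
deg <- evaluate_fixed_ranking(degree_ranking(net), annots, groups = nv$group)
ipn <- neighbor_voting(build_ipn(net), annots, folds = 3, seed = 7)

c(neighbor_voting = mean(nv$value),
  degree_only     = mean(deg$value),
  ipn             = mean(ipn$value))
#> neighbor_voting     degree_only             ipn
#>       0.6388678       0.7259792       0.6747050
cor(deg$value, nv$value, method = "spearman")
#> [1] 0.8507411
```

The numbers tell the story the package exists for: a gene-free degree
ranking (0.73) and a pair-information-free IPN (0.67) both "predict" as
well as or better than actual neighbor voting (0.64), and the per-group
correlation between degree-only and network AUROCs is 0.85 — on this
network, per-group performance is almost entirely explained by
multifunctionality bias. `bias_report()` tabulates these diagnostics,
`group_null()` attaches degree-corrected empirical p-values, and
`gba_audit()` runs the whole control battery at once (its `glance()` row
summarises the result).

All result objects are tibbles with `tidy()`, `glance()` and `autoplot()`
methods, so they compose directly with dplyr and ggplot2.

A command-line wrapper is provided for file-based workflows:

```sh
exec/gba-bias mf rank sets.gmt -o ranking.tsv
exec/gba-bias audit --replicates 200 --seed 7 net.tsv sets.gmt -o audit_out/
```

Inputs: GMT gene sets (optionally GAF 2.x + OBO with ancestor propagation),
TSV edge lists, dense TSV matrices, MatrixMarket sparse matrices, and
gene × sample expression TSVs for coexpression construction.

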