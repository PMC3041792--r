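---
title: "Multifunctionality bias in guilt-by-association prediction: models, controls, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multifunctionality bias in guilt-by-association prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbabias)
```

## The model

Guilt-by-association (GBA) prediction evaluates, for each annotation group
(a GO term, pathway, or disease gene set), how well a network-based score
ranks the group's members above non-members. The central confounder this
package addresses is *multifunctionality*: genes differ enormously in how
many groups they belong to, and because the same gene universe is reused
for every group, any fixed tendency to rank multifunctional genes highly
pays off across all groups simultaneously.

**Multifunctionality score.** For a universe of $N$ genes, a gene $g$'s
score is

$$\mathrm{MF}(g) \;=\; \sum_{i\,:\,g \in \mathrm{group}_i}
  \frac{1}{n_i \,(N - n_i)},$$

where $n_i$ is the size of group $i$. Ignoring the weights this is just the
number of annotations a gene has; the weights make small-group memberships
count for more.

**Why this ranking is AUROC-optimal.** For a strict gene ordering with rank
positions $r_g$ (1 = top), the AUROC of group $i$ can be written from the
Mann–Whitney rank-sum as an affine function of $\sum_{g \in i} r_g$.
Averaging over groups,

$$\overline{\mathrm{AUC}} \;=\; C \;-\;
  \frac{1}{|\mathcal{G}|}\sum_{g} r_g\,\mathrm{MF}(g),$$

a linear function of the positions with per-gene coefficients
$-\mathrm{MF}(g)$. It is maximized by assigning the top positions to the
largest coefficients, i.e. sorting by MF; ties in MF do not affect the
mean. The test suite verifies this against exhaustive permutation search on
universes of up to 7 genes. The analogous PPV@k-optimal list sorts by raw
annotation count, since a gene's marginal contribution to mean PPV@k is
proportional to its number of memberships and independent of the position
it fills.

**Degree as a proxy.** If gene $i$ takes part in an association assay with
propensity $p_i$ and pairs appear independently with probability
$\propto p_i p_j$, then the expected row sum (weighted node degree) of the
association matrix is proportional to $p_i$ times a constant. So node
degree recovers the propensity ranking, and the degree vector is also the
direction of the best rank-one (least-squares) approximation of the
association matrix. The *individual property network* (IPN) materializes
that approximation: score every pair by $d_i d_j$, keep the top pairs until
the kept count equals the original's edge count plus the $N$ self-pairs
("identity relationships" enter the sparsity budget), then drop the
self-pairs. Pairs with zero degree product are never kept — an isolated
gene cannot gain an edge from no information. Whether the network's
apparent performance survives the replacement of its edges by the IPN's is
the package's headline diagnostic.

**Neighbor voting.** A candidate gene $c$ is scored for a training set $T$
as

$$s(c) \;=\; \frac{\sum_{t \in T} R_c(t)}{\sum_{g \notin T,\, g \neq c} R_c(g)},$$

where $R_c(\cdot)$ ranks the association weights of $c$ across the
universe (ties averaged, higher weight = higher rank). Because the full
rank sum per candidate is constant, the score is a monotone function of
the numerator; the ratio form is kept as the definition. Cross-validation
is 3-fold by default: members are split by a seeded round-robin after a
shuffle, negatives are never split, and hidden members are evaluated
against all non-members.

**Degree-preserving null.** The significance question worth asking is not
"does the network beat a label permutation?" (which destroys the per-gene
degree structure) but "does it beat random networks in which every gene
keeps its exact degree?". Those are generated by attempted double-edge
swaps — pick edges $(a,b)$ and $(c,d)$, rewire to $(a,d),(c,b)$ unless a
self-loop or multi-edge would result — with $100 \times |E|$ attempts by
default. Replicates are shared across groups (one rewiring, all groups
evaluated), and the one-sided empirical p-value uses the add-one
estimator $(1 + \#\{s \ge \mathrm{obs}\})/(1 + R)$, with
Benjamini–Hochberg adjustment reported alongside. Self-loops and
multi-edges are forbidden in the null; weighted networks must be
binarized first (or label-permuted instead).

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `filter_by_size` bounds | 20–1000 | evaluation window for group sizes; smaller groups give unstable AUROCs, larger ones are uninformative |
| network `sparsity` | 0.005 | fraction of unordered gene pairs kept as edges in thresholding / coexpression |
| neighbor-voting `folds` | 3 | cross-validation folds; members only |
| `roc50` truncation | 50 false positives | top-of-list emphasis; equals plain AUROC when there are at most 50 negatives (the normalizer uses `min(50, #negatives) × #positives`) |
| `ppv_at_k` / PPV-optimal `k` | 50 | list depth at which precision is read |
| null `replicates` | 1000 | degree-preserving rewirings per null (desk-scale runs use 200) |
| `swap_factor` | 100 | attempted swaps per edge in each rewiring |
| `mf_skew` | 1 | concentration of synthetic annotation propensity |
| `rho` | 0 | target rank coupling between network propensity and MF |

## The synthetic generator

The generator emulates the two statistical features of real data the
method depends on, and deliberately nothing else:

1. **Heavy-tailed, heterogeneous annotation prevalence.** Each gene gets a
   standard-normal latent propensity $z_g$; group $j$ samples its members
   with probabilities $\propto \exp(s_j z_g)$, where the per-group skew
   $s_j$ is uniform on $[0, \texttt{mf\_skew}]$. The per-group modulation
   matters: real ontologies mix groups dominated by well-studied
   multifunctional genes with highly specific groups, and it is exactly
   this heterogeneity that produces the wide spread of per-group
   degree-ranking AUROCs seen in real data. With a single global skew the
   degree AUROCs compress into a narrow band and the characteristic
   correlation between degree-only and network performance is attenuated.
   Group sizes are log-uniform between their bounds.
2. **Prevalence-driven edges.** Network propensities are lognormal
   (`propensity_sd` on the log scale); with `rho > 0` their ranks are
   blended with the MF ranks through a Gaussian copula, so `rho` is
   interpretable as a rank-correlation target regardless of marginals.
   Edges are independent Bernoulli with probability $\propto p_i p_j$
   scaled to the target sparsity (capped at 1 with iterative rescaling);
   an exact-edge-count mode exists for tests that need fixed $|E|$.
   Planted modules overwrite within-group pairs at a stated density.
   With `degree_balance = TRUE` a module's members get their background
   edge probability lowered so their expected total degree matches the
   non-members' — the only way to realize "true associations with no
   degree footprint" when a dense clique would otherwise raise its
   members' degrees. Balancing is infeasible (and warned about) when the
   within-module degree already exceeds the background mean.
3. **Latent-factor expression.** Module genes load with weight $\lambda$
   on a shared factor plus $\sqrt{1-\lambda^2}$ Gaussian noise;
   non-module genes are pure noise.

What the generator does *not* emulate: scale-free degree tails, assay
noise models, annotation incompleteness, or ontology structure. Passing
tests on these fixtures therefore demonstrates that the algorithms behave
as specified under the prevalence model — not that any particular real
dataset is biased to a particular degree.

## Study conditions used in the packaged experiments

The acceptance script and the deepest tests run three fixed designs,
chosen once as representative desk-scale conditions:

- **Coupled regime** (bias signatures): 1000 genes, 100 groups of 20–100,
  `mf_skew = 2`, `rho = 0.9`, sparsity 0.04 (mean degree ≈ 40, a few
  percent of the universe, comparable to the per-gene partner fraction of
  dense interaction datasets). Here the per-group Spearman correlation
  between degree-ranking and neighbor-voting AUROCs is high (≈ 0.85–0.95)
  and the IPN reproduces the real network's mean AUROC to within 0.1.
- **Calibration regime**: 1000 genes, 0.5% sparsity, 50 groups,
  `rho = 0`, 200 degree-preserving replicates per group. Group-null
  p-values are checked for uniformity (Kolmogorov–Smirnov, α = 0.01):
  with no planted signal and no coupling, the real network is itself a
  draw from the degree-conditioned ensemble, so the p-values must be
  flat.
- **Planted regime** (true signal, no bias): 1000 genes, 30 disjoint-ish
  groups of 20 planted as full cliques on a 2% background with degree
  balancing. Neighbor voting approaches AUROC 1 while the IPN stays near
  chance; the gap (≥ 0.2 asserted, ≈ 0.5 observed) is what genuine
  association information looks like under these controls.

## Numerical and design choices

- **Tie handling.** Rankings carry a tie policy: `"average"` (midranks,
  the default, used by all metrics) or `"stable"` (input order, for
  byte-reproducible emitted lists). PPV@k resolves a tie block straddling
  the cutoff by its expected true-positive count; average precision
  resolves ties stably before evaluation.
- **Deterministic selection.** Every thresholding operation orders by
  descending value, then lexicographic gene pair — outputs are
  bit-identical across runs, which the audit-determinism test checks
  end to end through the CLI.
- **Zero scores never make edges.** Sparsified edges are a subset of
  positively scored input pairs; coexpression edges come from the
  positive correlation tail by default (`absolute = TRUE` for |r|), with
  an optional one-sided Fisher-transform p-value cut, pairwise-complete
  correlations, and a minimum overlap of 3 samples.
- **Self-association.** A candidate's own rank is excluded from the
  neighbor-voting denominator; the alternative (including it) shifts all
  scores by a candidate-specific constant and is not exposed.
- **Degenerate inputs.** Groups spanning the whole universe make the MF
  weight undefined and are excluded with a warning rather than clamped;
  empty networks yield chance-level scores everywhere; an all-zero degree
  vector has no IPN and errors.
- **Fold seeding.** Fold assignment derives from the run seed plus the
  group's column index, so observed and null evaluations share folds and
  a group's folds do not depend on which other groups are evaluated.
- **CCR protocol.** Balanced pools are built by partitioning non-members
  into blocks of the group's size (seeded shuffle, last block padded by
  resampling), classifying the top half of each pooled ranking as
  positive, and averaging across blocks.
- **"Dice-Jaccard" readings.** The link-similarity module exposes `dice`
  (factor-2 normalization, default), `jaccard`, `half_dice` (overlap over
  the plain sum of term counts, maximum 0.5) and `overlap_count`, always
  reporting the measure name, because the field's usage of the hyphenated
  term is ambiguous and the readings differ by a factor of two.
- **IPN budget reading.** "Same sparsity after adding identity
  relationships" is implemented as: select the top $|E| + N$ pairs among
  all pairs *including* self-pairs, then discard self-pairs. When degrees
  are heterogeneous nearly all self-pairs sit above the threshold and the
  edge count is close to $|E|$; under heavy ties the documented
  deterministic fill applies. A `count_self_pairs = FALSE` switch supports
  sensitivity analysis.
- **GAF/OBO scope.** Ancestor propagation follows `is_a` and `part_of`
  only; `NOT`-qualified rows are dropped; both propagated and flat modes
  are available since either could be a collection's convention.

## Limitations

- The degree-preserving null assumes a simple graph (no self-loops or
  multi-edges) and binary weights; for weighted networks only label
  permutation is offered.
- Empirical p-values at $R$ replicates are granular at $1/(R+1)$;
  calibration checks should use tests robust to that discreteness.
- The neighbor-voting implementation holds a dense $N \times N$ rank
  matrix in memory; it is intended for desk-scale universes (up to a few
  thousand genes), not genome-wide matrices.
- The optimal ranking is circular by construction: it is a control and an
  upper bound for prevalence-driven performance, never a prediction
  method.
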