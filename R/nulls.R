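# --- Degree-preserving and permutation null models ------------------------

#' Degree-preserving network randomization
#'
#' Rewires a binary network by attempted double-edge swaps — pick two edges
#' `(a,b)` and `(c,d)`, rewire to `(a,d)` and `(c,b)` unless a self-loop or
#' multi-edge would result — leaving every gene's degree exactly unchanged.
#' This is the null model behind the package's bias-corrected significance:
#' ordinary label permutation preserves the *multiset* of degrees but
#' reassigns them to genes, destroying the per-gene degree structure that
#' multifunctionality exploits; degree-preserving rewiring destroys only the
#' pair-specific associations.
#'
#' @param n A binary `gba_network` with at least 2 edges. Weighted input is
#'   an error (binarize first, or permute labels instead).
#' @param seed Integer seed.
#' @param swap_factor Attempted swaps per edge (default 100); total attempts
#'   are `swap_factor * |E|`.
#' @return A binary `gba_network` with the same per-gene degrees.
#' @export
degree_preserving_randomize <- function(n, seed = 1, swap_factor = 100) {
  stopifnot(inherits(n, "gba_network"))
  if (!n$binary) {
    abort("Degree-preserving rewiring needs a binary network; binarize (threshold_sparsify) or use permute_labels() for weighted input.")
  }
  genes <- rownames(n$weights)
  idx <- which(upper.tri(n$weights) & n$weights != 0, arr.ind = TRUE)
  if (nrow(idx) < 2) abort("Need at least 2 edges.")
  set.seed(seed)
  new_idx <- double_edge_swap_cpp(idx - 1L, length(genes),
                                  swap_factor * nrow(idx)) + 1L
  binary_from_pairs(genes, new_idx)
}

#' Gene-label permutation null
#'
#' Applies a random relabeling permutation to the genes of a network: the
#' graph structure (and so the sorted degree sequence) is untouched, but
#' which gene carries which degree is randomized. This is the "usual"
#' permutation null that degree-preserving rewiring improves upon.
#'
#' @param n A `gba_network`.
#' @param seed Integer seed.
#' @return A `gba_network` on the same universe.
#' @export
permute_labels <- function(n, seed = 1) {
  stopifnot(inherits(n, "gba_network"))
  genes <- rownames(n$weights)
  set.seed(seed)
  perm <- sample(length(genes))
  w <- n$weights[perm, perm]
  dimnames(w) <- list(genes, genes)
  as_network(w, binary = n$binary)
}

#' Per-group null distribution under degree-preserving randomization
#'
#' Re-runs a predictor on `replicates` degree-preserving rewirings of the
#' network and compares the observed per-group performance on the real
#' network against the resulting null samples. The rewired replicates are
#' shared across groups (one rewiring, all groups evaluated on it), which is
#' both cheaper and exactly the procedure of generating a collection of
#' degree-matched random matrices. The resulting empirical p-value asks: is
#' this group predicted better than expected from its genes' degrees (hence
#' multifunctionality) alone?
#'
#' @param n A binary `gba_network`.
#' @param a An [annotation_matrix()] on the same universe.
#' @param groups Character vector of group ids to test (default: all groups
#'   evaluable by the predictor).
#' @param predictor `"neighbor_voting"` (default) or `"degree_ranking"`
#'   (the latter is invariant under the null — useful as a control).
#' @param replicates Number of rewired replicates (default 1000).
#' @param seed Integer seed; replicate `r` is rewired with seed `seed + r`.
#' @param folds,metric,k Passed to the predictor.
#' @param swap_factor Passed to [degree_preserving_randomize()].
#' @return A tibble of class `gba_null`: per group, `observed`, `null_mean`,
#'   `null_sd`, `p` (add-one empirical, one-sided), `p_adj`
#'   (Benjamini-Hochberg across groups), `n_replicates`, and the null
#'   `samples` as a list column.
#' @export
group_null <- function(n, a, groups = NULL, predictor = c("neighbor_voting",
                                                          "degree_ranking"),
                       replicates = 1000, seed = 1, folds = 3,
                       metric = "auc", k = 50, swap_factor = 100) {
  stopifnot(inherits(n, "gba_network"), inherits(a, "annotation_matrix"))
  check_shared_universe(n, a)
  predictor <- match.arg(predictor)
  if (replicates < 1) abort("`replicates` must be >= 1.")
  run <- function(net) {
    ev <- if (predictor == "neighbor_voting") {
      neighbor_voting(net, a, folds = folds, seed = seed, metric = metric,
                      k = k, groups = groups)
    } else {
      evaluate_fixed_ranking(degree_ranking(net), a, metric = metric, k = k,
                             groups = groups)
    }
    stats::setNames(ev$value, ev$group)
  }
  observed <- run(n)
  samples <- matrix(NA_real_, replicates, length(observed),
                    dimnames = list(NULL, names(observed)))
  for (r in seq_len(replicates)) {
    net_r <- degree_preserving_randomize(n, seed = seed + r,
                                         swap_factor = swap_factor)
    samples[r, ] <- run(net_r)[names(observed)]
  }
  p <- vapply(names(observed), function(g) {
    empirical_pvalue(observed[[g]], samples[, g])
  }, 0)
  out <- tibble::tibble(
    group = names(observed),
    size = unname(group_sizes(a)[names(observed)]),
    observed = unname(observed),
    null_mean = unname(colMeans(samples)),
    null_sd = unname(apply(samples, 2, stats::sd)),
    p = unname(p),
    p_adj = stats::p.adjust(unname(p), method = "BH"),
    n_replicates = replicates,
    samples = lapply(seq_along(observed), function(j) samples[, j])
  )
  structure(out, class = c("gba_null", class(tibble::tibble())),
            predictor = predictor, metric = metric, seed = seed,
            swap_factor = swap_factor)
}

#' @export
print.gba_null <- function(x, ...) {
  cat(sprintf(
    "<gba_null> %d group(s), %d degree-preserving replicates, predictor '%s'\n",
    nrow(x), x$n_replicates[1], attr(x, "predictor")))
  NextMethod()
}

#' @export
glance.gba_null <- function(x, ...) {
  tibble::tibble(
    predictor = attr(x, "predictor"),
    metric = attr(x, "metric"),
    n_groups = nrow(x),
    n_replicates = x$n_replicates[1],
    mean_observed = mean(x$observed),
    mean_null = mean(x$null_mean),
    n_significant = sum(x$p < 0.05),
    seed = attr(x, "seed")
  )
}

#' @export
tidy.gba_null <- function(x, ...) {
  tibble::as_tibble(x)[setdiff(names(x), "samples")]
}

#' Multifunctionality bias report for a network analysis
#'
#' The one-stop diagnostic table: for every annotation group, the AUROC
#' attained by the node-degree ranking (no association information) next to
#' the AUROC of the actual predictor, plus the group's "extremity"
#' `|degree AUC - 0.5|` (groups whose members are unusually multi- OR
#' mono-functional are both flagged by high extremity — the triangular
#' dependence). Global diagnostics (Spearman correlations between the two
#' AUC columns and between node degree and multifunctionality score, and the
#' two mean AUCs) are available through [glance()].
#'
#' @param n A `gba_network`.
#' @param a An [annotation_matrix()] on the same universe.
#' @param predictor `"neighbor_voting"` or a precomputed `gba_evaluation`
#'   (e.g. from a user's own method) whose groups are matched by id.
#' @param seed,folds,metric,k Passed to [neighbor_voting()] when it is the
#'   predictor.
#' @return A tibble of class `bias_report`: `group`, `size`, `degree_auc`,
#'   `predictor_auc`, `extremity`.
#' @export
bias_report <- function(n, a, predictor = "neighbor_voting", seed = 1,
                        folds = 3, metric = "auc", k = 50) {
  stopifnot(inherits(n, "gba_network"), inherits(a, "annotation_matrix"))
  check_shared_universe(n, a)
  deg_ev <- evaluate_fixed_ranking(degree_ranking(n), a, metric = metric,
                                   k = k)
  pred_ev <- if (inherits(predictor, "gba_evaluation")) {
    predictor
  } else if (identical(predictor, "neighbor_voting")) {
    neighbor_voting(n, a, folds = folds, seed = seed, metric = metric, k = k)
  } else if (identical(predictor, "degree_ranking")) {
    deg_ev
  } else {
    abort("`predictor` must be 'neighbor_voting', 'degree_ranking', or a gba_evaluation.")
  }
  common <- intersect(deg_ev$group, pred_ev$group)
  deg_auc <- stats::setNames(deg_ev$value, deg_ev$group)[common]
  pred_auc <- stats::setNames(pred_ev$value, pred_ev$group)[common]
  mf <- multifunctionality_scores(a)
  deg <- node_degree(n)
  out <- tibble::tibble(
    group = common,
    size = unname(group_sizes(a)[common]),
    degree_auc = unname(deg_auc),
    predictor_auc = unname(pred_auc),
    extremity = abs(unname(deg_auc) - 0.5)
  )
  # constant columns (e.g. uniform-degree networks) have no defined rank
  # correlation; report NA rather than warn
  safe_spearman <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y, method = "spearman")
  }
  structure(out, class = c("bias_report", class(tibble::tibble())),
            predictor = if (inherits(predictor, "gba_evaluation"))
              attr(predictor, "predictor") else predictor,
            metric = metric,
            cor_auc = if (identical(unname(deg_auc), unname(pred_auc)) &&
                          stats::sd(deg_auc) == 0) 1.0 else
              safe_spearman(deg_auc, pred_auc),
            cor_degree_mf = safe_spearman(deg$degree, mf$score),
            mean_degree_auc = mean(deg_auc),
            mean_predictor_auc = mean(pred_auc),
            seed = seed)
}

#' @export
print.bias_report <- function(x, ...) {
  cat(sprintf(
    "<bias_report> %d group(s); mean degree AUC %.3f, mean predictor AUC %.3f\n",
    nrow(x), attr(x, "mean_degree_auc"), attr(x, "mean_predictor_auc")))
  cat(sprintf(
    "  Spearman(degree AUC, predictor AUC) = %.3f; Spearman(degree, MF) = %.3f\n",
    attr(x, "cor_auc"), attr(x, "cor_degree_mf")))
  NextMethod()
}

#' @export
glance.bias_report <- function(x, ...) {
  tibble::tibble(
    predictor = attr(x, "predictor"),
    metric = attr(x, "metric"),
    n_groups = nrow(x),
    mean_degree_auc = attr(x, "mean_degree_auc"),
    mean_predictor_auc = attr(x, "mean_predictor_auc"),
    cor_auc = attr(x, "cor_auc"),
    cor_degree_mf = attr(x, "cor_degree_mf")
  )
}

#' @export
tidy.bias_report <- function(x, ...) tibble::as_tibble(x)
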