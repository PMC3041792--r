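#' Per-gene multifunctionality scores
#'
#' The multifunctionality score of a gene is the sum, over the annotation
#' groups it belongs to, of `1 / (n_in * n_out)`, where `n_in` is the number
#' of universe genes inside the group and `n_out` the number outside. It is a
#' weighted count of a gene's functions: membership in a small group counts
#' for more, and the weighting makes ranking genes by this score the fixed
#' ranking that maximizes mean AUROC over all groups (see
#' [optimal_ranking_auc()]).
#'
#' Groups annotating the whole universe (`n_out = 0`) make the weight
#' undefined and are excluded with a warning, as are empty groups.
#'
#' @param a An [annotation_matrix()].
#' @return A tibble of class `mf_scores` with columns `gene`, `score`
#'   (the multifunctionality score) and `n_groups` (raw annotation count),
#'   in universe order. The ids of excluded groups are kept in attribute
#'   `excluded_groups`.
#' @examples
#' a <- annotation_matrix(matrix(c(TRUE, FALSE, FALSE), 3, 1,
#'   dimnames = list(c("g1", "g2", "g3"), "S1")))
#' multifunctionality_scores(a)  # g1 scores 1/(1*2)
#' @export
multifunctionality_scores <- function(a) {
  stopifnot(inherits(a, "annotation_matrix"))
  m <- unclass(a)
  n <- nrow(m)
  n_in <- colSums(m)
  valid <- n_in >= 1 & n_in < n
  if (any(!valid)) {
    warn(sprintf(
      "%d group(s) with no members or spanning the whole universe excluded from multifunctionality scoring.",
      sum(!valid)
    ))
  }
  mv <- m[, valid, drop = FALSE]
  w <- 1 / (n_in[valid] * (n - n_in[valid]))
  score <- as.numeric(mv %*% w)
  out <- tibble::tibble(
    gene = rownames(m),
    score = score,
    n_groups = as.integer(rowSums(mv))
  )
  structure(out, class = c("mf_scores", class(tibble::tibble())),
            excluded_groups = colnames(m)[!valid])
}

#' AUROC-optimal fixed gene ranking
#'
#' Returns the single gene ordering that maximizes the mean AUROC, averaged
#' over all annotation groups, when the same list is used to "predict"
#' membership in every group. This optimum is attained by sorting genes by
#' decreasing multifunctionality score: mean AUROC is linear in the rank
#' positions with per-gene coefficients equal to the multifunctionality
#' weights, so any other order can only do worse. The ranking is circular by
#' construction (it is optimized against the annotations themselves) — its
#' use is as a bias control, not a prediction method.
#'
#' @param a An [annotation_matrix()].
#' @param tie_policy Passed to [gene_ranking()]. Unannotated genes all score
#'   0 and therefore rank last (tied).
#' @return A [gene_ranking()] whose scores are multifunctionality scores.
#' @export
optimal_ranking_auc <- function(a, tie_policy = c("average", "stable")) {
  mf <- multifunctionality_scores(a)
  gene_ranking(stats::setNames(mf$score, mf$gene), match.arg(tie_policy))
}

#' PPV-optimized fixed gene ranking
#'
#' Greedy construction of a fixed ranking targeting mean positive predictive
#' value in the top `k` (PPV@k) instead of AUROC: list positions are filled
#' in order, each time choosing the gene with the largest summed increment to
#' mean PPV@k across groups — which at every step is the gene annotated to
#' the most groups. Ties are broken by multifunctionality score, then gene
#' id. Positions beyond `k` do not affect PPV@k and are filled by
#' multifunctionality order.
#'
#' @param a An [annotation_matrix()].
#' @param k PPV threshold (list depth), default 50.
#' @param tie_policy Tie policy recorded on the result (the construction
#'   itself is deterministic).
#' @return A [gene_ranking()] (scores are the internal selection keys,
#'   strictly decreasing).
#' @export
optimal_ranking_ppv <- function(a, k = 50, tie_policy = c("average", "stable")) {
  stopifnot(inherits(a, "annotation_matrix"))
  if (k < 1) abort("`k` must be >= 1.")
  n <- nrow(a)
  if (k > n) abort("`k` exceeds the universe size.")
  mf <- multifunctionality_scores(a)
  n_in <- group_sizes(a)
  valid <- n_in >= 1 & n_in < n
  counts <- rowSums(unclass(a)[, valid, drop = FALSE])
  # Greedy: marginal PPV@k gain of a gene is proportional to its annotation
  # count, independent of the position it fills, so the greedy order sorts by
  # count with the documented tie-breaks.
  ord_key <- order(-counts, -mf$score, mf$gene)
  genes <- mf$gene[ord_key]
  topk <- genes[seq_len(k)]
  rest_pool <- setdiff(mf$gene, topk)
  mf_rest <- mf[match(rest_pool, mf$gene), ]
  rest <- rest_pool[order(-mf_rest$score, mf_rest$gene)]
  ordered <- c(topk, rest)
  gene_ranking(stats::setNames(seq(n, 1), ordered), match.arg(tie_policy))
}

#' Rank annotation groups by the multifunctionality of their members
#'
#' Evaluates a fixed gene ranking as a "predictor" of membership in every
#' group and returns the per-group AUROC, sorted descending. With the
#' AUROC-optimal ranking this orders groups by how multifunctional their
#' member genes are — the top groups are the ones most predictable from
#' annotation prevalence alone.
#'
#' @param a An [annotation_matrix()].
#' @param r A [gene_ranking()] covering the universe of `a`; defaults to
#'   [optimal_ranking_auc()] of `a`.
#' @return A tibble: `group`, `size`, `auc`, sorted by decreasing `auc`.
#' @export
group_multifunctionality <- function(a, r = optimal_ranking_auc(a)) {
  ev <- evaluate_fixed_ranking(r, a, metric = "auc")
  dplyr::arrange(tibble::as_tibble(ev)[c("group", "size", "value")],
                 dplyr::desc(.data$value)) |>
    dplyr::rename(auc = "value")
}
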