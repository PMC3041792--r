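# --- Ranking-based evaluation metrics -------------------------------------
#
# All metrics take a logical label vector and a numeric score vector of equal
# length (higher score = better candidate) and resolve tied scores by the
# average (midrank) convention unless noted.

check_labels_scores <- function(labels, scores) {
  labels <- as.logical(labels)
  if (length(labels) != length(scores)) {
    abort("`labels` and `scores` must have equal length.")
  }
  if (anyNA(labels) || anyNA(scores)) abort("NA in labels or scores.")
  if (!any(labels) || all(labels)) {
    abort("Need at least one positive and one negative.")
  }
  labels
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' The fraction of (positive, negative) pairs in which the positive is
#' scored higher, ties counting one half. 0.5 is chance, 1 a perfect
#' ranking.
#'
#' @param labels Logical vector of class memberships.
#' @param scores Numeric candidate scores, higher ranked first.
#' @return AUROC in \[0, 1\].
#' @export
auc_score <- function(labels, scores) {
  labels <- check_labels_scores(labels, scores)
  r <- rank(scores, ties.method = "average")
  p <- sum(labels)
  n <- sum(!labels)
  (sum(r[labels]) - p * (p + 1) / 2) / (p * n)
}

#' ROC area truncated at the n-th false positive (ROC50)
#'
#' Scans the ranking from the top and accumulates, for each of the first
#' `n_fp` negatives encountered, the number of positives ranked above it
#' (ties counting one half); the sum is normalized by
#' `min(n_fp, #negatives) * #positives` so a perfect ranking scores 1 and,
#' when there are at most `n_fp` negatives, the value equals [auc_score()].
#' The measure focuses on the top of the list, where predictions would be
#' followed up.
#'
#' @inheritParams auc_score
#' @param n_fp Number of false positives at which to truncate (default 50).
#' @return Truncated, normalized ROC area in \[0, 1\].
#' @export
roc50 <- function(labels, scores, n_fp = 50) {
  labels <- check_labels_scores(labels, scores)
  if (n_fp < 1) abort("`n_fp` must be >= 1.")
  p <- sum(labels)
  neg_scores <- scores[!labels]
  m <- min(n_fp, length(neg_scores))
  # the first m negatives in rank order = the m highest-scoring negatives
  top_neg <- sort(neg_scores, decreasing = TRUE)[seq_len(m)]
  pos_scores <- scores[labels]
  hits <- vapply(top_neg, function(ns) {
    sum(pos_scores > ns) + 0.5 * sum(pos_scores == ns)
  }, 0)
  sum(hits) / (m * p)
}

#' Positive predictive value in the top k (PPV@k)
#'
#' The fraction of the top `k` ranked genes that are positives. A tie block
#' straddling rank `k` contributes its expected number of positives under
#' random resolution of the ties (slots in the block times the block's
#' positive fraction).
#'
#' @inheritParams auc_score
#' @param k List depth (default 50); must not exceed the number of genes.
#' @return PPV in \[0, 1\].
#' @export
ppv_at_k <- function(labels, scores, k = 50) {
  labels <- as.logical(labels)
  if (k <= 0) abort("`k` must be positive.")
  if (k > length(scores)) abort("`k` exceeds the number of genes.")
  if (anyNA(labels) || anyNA(scores)) abort("NA in labels or scores.")
  ord <- order(scores, decreasing = TRUE)
  s_sorted <- scores[ord]
  l_sorted <- labels[ord]
  if (k == length(scores)) return(sum(l_sorted) / k)
  cutoff <- s_sorted[k]
  above <- s_sorted > cutoff
  in_block <- s_sorted == cutoff
  tp <- sum(l_sorted[above])
  slots <- k - sum(above)
  block_pos <- sum(l_sorted[in_block])
  block_n <- sum(in_block)
  (tp + slots * block_pos / block_n) / k
}

#' Area under the precision-recall curve (average precision)
#'
#' Mean over positives, taken in rank order, of the precision at each
#' positive's rank. Ties are resolved to a strict order (stable in input
#' order) before evaluation. Strongly rewards positives at the very top of
#' the ranking, and unlike AUROC its chance level depends on the positive
#' prevalence.
#'
#' @inheritParams auc_score
#' @return Average precision in \[0, 1\].
#' @export
aup <- function(labels, scores) {
  labels <- check_labels_scores(labels, scores)
  ord <- order(-scores)                    # stable: ties by input order
  l <- labels[ord]
  cum_tp <- cumsum(l)
  prec_at_pos <- cum_tp[l] / which(l)
  mean(prec_at_pos)
}

#' Correct classification rate on a balanced pool
#'
#' For a pool constructed to contain equally many positives and negatives,
#' predicts the top half of the ranking as positive and returns
#' `(TP + TN) / total`. Errors on unbalanced input: use
#' [balanced_ccr_protocol()] to build and average balanced pools.
#'
#' @inheritParams auc_score
#' @return CCR in \[0, 1\].
#' @export
ccr <- function(labels, scores) {
  labels <- check_labels_scores(labels, scores)
  p <- sum(labels)
  if (p * 2 != length(labels)) {
    abort("CCR needs a balanced pool (as many negatives as positives); see balanced_ccr_protocol().")
  }
  ord <- order(-scores, seq_along(scores)) # stable tie resolution
  predicted_pos <- seq_along(labels) %in% ord[seq_len(p)]
  tp <- sum(predicted_pos & labels)
  tn <- sum(!predicted_pos & !labels)
  (tp + tn) / length(labels)
}

#' Balanced-pool CCR protocol
#'
#' Emulates piecewise balanced evaluation: non-members of the group are
#' partitioned (after a seeded shuffle) into blocks of the group's size, the
#' last block padded by resampling earlier non-members; each block is pooled
#' with the group, scored, and its [ccr()] computed; the average across
#' blocks is returned, so every gene is tested once.
#'
#' @param scores Named numeric vector of candidate scores covering the
#'   universe.
#' @param a An [annotation_matrix()] on the same universe.
#' @param group Group id (column of `a`).
#' @param seed Integer seed for the block shuffle.
#' @return A tibble with `group`, `ccr` (the block average) and `n_blocks`.
#' @export
balanced_ccr_protocol <- function(scores, a, group, seed = 1) {
  stopifnot(inherits(a, "annotation_matrix"))
  if (!group %in% colnames(a)) abort(sprintf("Unknown group: %s", group))
  uni <- rownames(a)
  if (is.null(names(scores)) || !all(uni %in% names(scores))) {
    abort("`scores` must be named and cover the universe.")
  }
  members <- uni[a[, group]]
  others <- setdiff(uni, members)
  s <- length(members)
  if (s > length(others)) {
    abort("Group larger than half the universe; balanced pools impossible.")
  }
  set.seed(seed)
  shuffled <- sample(others)
  n_blocks <- ceiling(length(others) / s)
  vals <- vapply(seq_len(n_blocks), function(b) {
    block <- shuffled[((b - 1) * s + 1):min(b * s, length(shuffled))]
    if (length(block) < s) {
      pad <- sample(setdiff(shuffled, block), s - length(block))
      block <- c(block, pad)
    }
    pool <- c(members, block)
    ccr(pool %in% members, scores[pool])
  }, 0)
  tibble::tibble(group = group, ccr = mean(vals), n_blocks = n_blocks)
}

#' Empirical p-value with the add-one estimator
#'
#' `(1 + #\{samples >= observed\}) / (1 + n)`: the permutation-test
#' estimator, one-sided (larger observed = smaller p), never exactly zero.
#'
#' @param observed Observed statistic.
#' @param samples Numeric vector of null samples.
#' @return p-value in (0, 1\].
#' @export
empirical_pvalue <- function(observed, samples) {
  if (length(samples) < 1) abort("Need at least one null sample.")
  if (anyNA(samples) || is.na(observed)) abort("NA in inputs.")
  (1 + sum(samples >= observed)) / (1 + length(samples))
}

# Dispatch a metric by name.
metric_fun <- function(metric, k = 50) {
  switch(metric,
    auc = auc_score,
    roc50 = function(l, s) roc50(l, s, n_fp = k),
    ppv = function(l, s) ppv_at_k(l, s, k = min(k, length(s))),
    aup = aup,
    abort(sprintf("Unknown metric: %s", metric))
  )
}
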