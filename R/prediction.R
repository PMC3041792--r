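# --- Guilt-by-association prediction and evaluation -----------------------

new_evaluation <- function(tbl, metric, predictor, folds = NA_integer_,
                           seed = NA_integer_) {
  structure(tbl, class = c("gba_evaluation", class(tibble::tibble())),
            metric = metric, predictor = predictor, folds = folds,
            seed = seed)
}

#' @export
print.gba_evaluation <- function(x, ...) {
  cat(sprintf("<gba_evaluation> predictor '%s', metric '%s', %d group(s), mean %.4f\n",
              attr(x, "predictor"), attr(x, "metric"), nrow(x),
              mean(x$value)))
  NextMethod()
}

#' @export
glance.gba_evaluation <- function(x, ...) {
  tibble::tibble(
    predictor = attr(x, "predictor"),
    metric = attr(x, "metric"),
    n_groups = nrow(x),
    mean_value = mean(x$value),
    sd_value = stats::sd(x$value),
    folds = attr(x, "folds"),
    seed = attr(x, "seed")
  )
}

#' @export
tidy.gba_evaluation <- function(x, ...) tibble::as_tibble(x)

# Per-candidate association ranks: R[c, j] = rank of weight w(c, j) among
# gene c's associations to all genes but itself (ties averaged, higher
# weight = higher rank). R[c, c] = 0.
association_ranks <- function(n) {
  w <- n$weights
  diag(w) <- NA
  r <- t(apply(w, 1, rank, ties.method = "average", na.last = "keep"))
  r[is.na(r)] <- 0
  dimnames(r) <- dimnames(n$weights)
  r
}

#' Neighbor-voting candidate scores for one training set
#'
#' Scores every gene outside the training set as the sum of its association
#' ranks to the training genes divided by the sum of its association ranks
#' to all non-training genes (itself excluded). Ranks are computed per
#' candidate across the whole universe with ties averaged, so a weighted and
#' a binary network are handled uniformly and an empty network gives every
#' candidate the same score.
#'
#' @param n A `gba_network`.
#' @param train Character vector of training-positive gene ids.
#' @param ranks Optional precomputed matrix from `association_ranks()`
#'   (internal use, avoids recomputation across folds).
#' @param total_ranks Optional precomputed `rowSums(ranks)` (internal use).
#' @return Named numeric vector of scores over the non-training genes.
#' @export
neighbor_voting_scores <- function(n, train, ranks = NULL,
                                   total_ranks = NULL) {
  stopifnot(inherits(n, "gba_network"))
  uni <- rownames(n$weights)
  if (!all(train %in% uni)) abort("Training genes outside the universe.")
  r <- ranks %||% association_ranks(n)
  tot <- total_ranks %||% rowSums(r)
  cand <- setdiff(uni, train)
  num <- rowSums(r[cand, train, drop = FALSE])
  non_train_sum <- tot[cand] - num         # self rank is 0
  score <- num / non_train_sum
  score[non_train_sum == 0] <- 0
  score
}

# Seeded round-robin fold assignment over shuffled positives.
# Returns an integer vector of fold indices (1..folds) named by positive.
make_folds <- function(positives, folds, seed) {
  set.seed(seed)
  shuffled <- sample(positives)
  stats::setNames(rep_len(seq_len(folds), length(shuffled)), shuffled)
}

#' Neighbor-voting prediction with cross-validation
#'
#' For every annotation group, the member genes are split into `folds`
#' cross-validation folds (seeded round-robin after a shuffle; negatives are
#' never split). In each fold the held-out members are hidden, every
#' non-training gene is scored by [neighbor_voting_scores()], and the hidden
#' members are evaluated against the non-member genes with the requested
#' metric; the per-group value is the unweighted mean over folds.
#'
#' @param n A `gba_network`.
#' @param a An [annotation_matrix()] on the same universe.
#' @param folds Number of cross-validation folds (default 3).
#' @param seed Integer seed controlling fold assignment.
#' @param metric One of `"auc"`, `"roc50"`, `"ppv"`, `"aup"`.
#' @param k Threshold parameter for `"roc50"` / `"ppv"`.
#' @param groups Optional subset of group ids to evaluate (default all).
#'   Groups with fewer members than `folds`, or spanning the universe, are
#'   skipped with a message.
#' @return A `gba_evaluation` tibble: `group`, `size`, `metric`, `value`,
#'   `n_folds`.
#' @export
neighbor_voting <- function(n, a, folds = 3, seed = 1, metric = "auc",
                            k = 50, groups = NULL) {
  stopifnot(inherits(n, "gba_network"), inherits(a, "annotation_matrix"))
  check_shared_universe(n, a)
  groups <- groups %||% colnames(a)
  if (!all(groups %in% colnames(a))) abort("Unknown group id(s).")
  uni <- rownames(a)
  ranks <- association_ranks(n)
  total_ranks <- rowSums(ranks)
  fn <- metric_fun(metric, k)
  sz <- group_sizes(a)[groups]
  skip <- sz < folds | sz >= length(uni)
  if (any(skip)) {
    inform(sprintf(
      "neighbor_voting: skipping %d group(s) with fewer members than folds (or spanning the universe).",
      sum(skip)
    ))
  }
  eval_groups <- groups[!skip]
  vals <- vapply(eval_groups, function(g) {
    members <- uni[a[, g]]
    fold_of <- make_folds(members, folds, seed = seed + match(g, colnames(a)))
    non_members <- setdiff(uni, members)
    fold_vals <- vapply(seq_len(folds), function(f) {
      hidden <- names(fold_of)[fold_of == f]
      train <- setdiff(members, hidden)
      sc <- neighbor_voting_scores(n, train, ranks = ranks,
                                   total_ranks = total_ranks)
      pool <- c(hidden, non_members)
      fn(pool %in% hidden, sc[pool])
    }, 0)
    mean(fold_vals)
  }, 0)
  new_evaluation(
    tibble::tibble(group = eval_groups, size = unname(sz[!skip]),
                   metric = metric, value = unname(vals),
                   n_folds = folds),
    metric = metric, predictor = "neighbor_voting", folds = folds, seed = seed
  )
}

#' Evaluate a fixed gene ranking against annotation groups
#'
#' Uses one gene ordering as the score vector for every group, with no
#' cross-validation (the ranking uses no group-specific training): group
#' members are the positives, all other universe genes the negatives. This
#' is how node-degree rankings and the multifunctionality-optimal ranking
#' are scored, and how an externally supplied candidate list (e.g. disease
#' gene sets) is audited.
#'
#' @param r A [gene_ranking()] covering the universe of `a`.
#' @param a An [annotation_matrix()].
#' @param metric,k As in [neighbor_voting()].
#' @param groups Optional subset of groups (default all non-degenerate ones).
#' @return A `gba_evaluation` tibble.
#' @export
evaluate_fixed_ranking <- function(r, a, metric = "auc", k = 50,
                                   groups = NULL) {
  stopifnot(inherits(r, "gene_ranking"), inherits(a, "annotation_matrix"))
  uni <- rownames(a)
  sc <- ranking_scores(r, uni)
  groups <- groups %||% colnames(a)
  if (!all(groups %in% colnames(a))) abort("Unknown group id(s).")
  sz <- group_sizes(a)[groups]
  keep <- sz >= 1 & sz < length(uni)
  fn <- metric_fun(metric, k)
  vals <- vapply(groups[keep], function(g) fn(a[, g], sc), 0)
  new_evaluation(
    tibble::tibble(group = groups[keep], size = unname(sz[keep]),
                   metric = metric, value = unname(vals),
                   n_folds = 0L),
    metric = metric, predictor = "fixed_ranking"
  )
}

#' Keep only groups with at least one within-group edge
#'
#' Groups whose members share no association at all cannot be learned by a
#' network method; filtering them out removes degenerate chance-level rows
#' from evaluations.
#'
#' @param n A `gba_network`.
#' @param a An [annotation_matrix()] on the same universe.
#' @return Character vector of learnable group ids.
#' @export
learnable_filter <- function(n, a) {
  stopifnot(inherits(n, "gba_network"), inherits(a, "annotation_matrix"))
  check_shared_universe(n, a)
  w <- n$weights != 0
  keep <- vapply(colnames(a), function(g) {
    idx <- which(a[, g])
    length(idx) >= 2 && any(w[idx, idx])
  }, TRUE)
  colnames(a)[keep]
}
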