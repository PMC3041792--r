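#' Individual property network (IPN)
#'
#' Builds the network obtained from the self-outer product of the node-degree
#' vector: every pair `(i, j)` is scored `d_i * d_j` and the top-scoring
#' pairs are kept so that the result matches the input's sparsity after
#' self-pairs ("identity relationships") are added to the budget; self-pairs
#' are then discarded from the returned binary network. The degree vector is
#' the least-squares rank-one approximation direction of the association
#' matrix, so the IPN is the best network reconstruction that uses only
#' per-gene information — it contains no pair-specific association at all.
#' Any prediction performance obtained from an IPN is attributable to
#' multifunctionality (prevalence) bias alone.
#'
#' @param n A `gba_network`.
#' @param count_self_pairs If `TRUE` (default), the `|universe|` self-pairs
#'   participate in the sparsity budget (they occupy the top of the
#'   degree-product ordering) before being dropped; `FALSE` disables this
#'   accounting for sensitivity analysis.
#' @return A binary `gba_network` whose degree ranking reproduces the
#'   input's.
#' @export
build_ipn <- function(n, count_self_pairs = TRUE) {
  stopifnot(inherits(n, "gba_network"))
  d <- rowSums(n$weights)
  if (all(d == 0)) abort("All node degrees are zero; no IPN definable.")
  genes <- rownames(n$weights)
  score <- outer(d, d)
  dimnames(score) <- list(genes, genes)
  budget <- network_edge_count(n) + if (count_self_pairs) length(genes) else 0
  pairs <- select_top_pairs(score, budget, include_self = count_self_pairs)
  binary_from_pairs(genes, pairs)
}

#' Greedy shared-function network
#'
#' Builds a small network whose edges join gene pairs with many shared
#' annotation groups, reweighting each group by the inverse of one plus the
#' number of times it has already supported an added edge. Repeatedly adds
#' the unconnected pair maximizing the summed reweighted overlap, updating
#' usage counts after each addition. This is the construction used to stress
#' precision-recall style metrics: a handful of edges among highly
#' multifunctional genes is enough to produce non-trivial average precision.
#'
#' @param a An [annotation_matrix()].
#' @param n_edges Number of edges to add (default 100).
#' @return A binary `gba_network` on the universe of `a`. If fewer pairs
#'   share any group than `n_edges`, all scoring pairs are returned with a
#'   warning.
#' @export
build_shared_function_network <- function(a, n_edges = 100) {
  stopifnot(inherits(a, "annotation_matrix"))
  if (n_edges < 1) abort("`n_edges` must be >= 1.")
  m <- unclass(a) * 1
  genes <- rownames(m)
  ng <- length(genes)
  used <- rep(0, ncol(m))
  sel <- matrix(0L, 0, 2)
  taken <- matrix(FALSE, ng, ng)
  for (step in seq_len(n_edges)) {
    s <- m %*% (t(m) * (1 / (1 + used)))   # pair score = sum_g shared 1/(1+used_g)
    diag(s) <- -Inf
    s[taken] <- -Inf
    best <- select_top_pairs(s, 1)
    if (nrow(best) == 0 || s[best] <= 0) {
      warn(sprintf(
        "Only %d pair(s) share any group; returning %d edge(s).",
        step - 1L, step - 1L
      ))
      break
    }
    i <- best[1, 1]; j <- best[1, 2]
    sel <- rbind(sel, c(i, j))
    taken[i, j] <- TRUE; taken[j, i] <- TRUE
    shared <- m[i, ] & m[j, ]
    used <- used + shared
  }
  binary_from_pairs(genes, sel)
}
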