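#' Construct an expression matrix
#'
#' @param values Numeric matrix, genes in rows (unique rownames), samples in
#'   columns (unique colnames); missing values allowed. At least 3 samples
#'   are required for correlation-based network construction.
#' @return An object of class `expression_matrix` (a validated matrix).
#' @export
expression_matrix <- function(values) {
  if (!is.matrix(values)) abort("`values` must be a matrix.")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    abort("`values` must have unique gene rownames.")
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("sample%d", seq_len(ncol(values)))
  }
  if (ncol(values) < 3) abort("At least 3 samples are required.")
  structure(values, class = c("expression_matrix", "matrix", "array"))
}

#' Read an expression TSV (first column gene id, header = sample ids)
#'
#' @param path File path.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(d[-1])
  rownames(m) <- as.character(d[[1]])
  expression_matrix(m)
}

#' Build a binary coexpression network
#'
#' Pearson correlations are computed over pairwise-complete samples (pairs
#' with fewer than `min_overlap` shared samples, and genes with constant
#' expression, contribute no edges). An edge is kept iff its correlation is
#' in the top `sparsity` fraction of all `n (n - 1) / 2` gene pairs AND, if
#' `max_fisher_p` is given, its one-sided Fisher-transform p-value is at most
#' that bound — whichever criterion is more stringent wins.
#'
#' @param e An [expression_matrix()].
#' @param sparsity Fraction of gene pairs to keep, in (0, 1); default 0.5%.
#' @param max_fisher_p Optional upper bound on the one-sided p-value of the
#'   Fisher z-transformed correlation.
#' @param absolute Select edges by `|r|` instead of the positive tail.
#' @return A binary `gba_network` on the expression genes.
#' @export
build_coexpression <- function(e, sparsity = 0.005, max_fisher_p = NULL,
                               absolute = FALSE) {
  stopifnot(inherits(e, "expression_matrix"))
  if (sparsity <= 0 || sparsity >= 1) abort("`sparsity` must be in (0, 1).")
  x <- t(unclass(e))                       # samples x genes
  suppressWarnings(r <- stats::cor(x, use = "pairwise.complete.obs"))
  n_obs <- crossprod(!is.na(x))            # shared samples per pair
  min_overlap <- 3
  r[n_obs < min_overlap] <- NA
  if (anyNA(r[upper.tri(r)])) {
    inform(sprintf(
      "build_coexpression: %d gene pair(s) with undefined correlation (constant gene or < %d shared samples) carry no edges.",
      sum(is.na(r[upper.tri(r)])), min_overlap
    ))
  }
  score <- if (absolute) abs(r) else r
  score[is.na(score)] <- -Inf
  diag(score) <- -Inf
  if (!is.null(max_fisher_p)) {
    z <- atanh(pmin(pmax(r, -1 + 1e-15), 1 - 1e-15))
    pv <- stats::pnorm(z * sqrt(pmax(n_obs - 3, 0)), lower.tail = FALSE)
    score[is.na(pv) | pv > max_fisher_p] <- -Inf
  }
  ng <- ncol(x)
  k <- floor(sparsity * ng * (ng - 1) / 2)
  pairs <- select_top_pairs(score, k)
  if (nrow(pairs) > 0) {
    vals <- score[pairs]
    pairs <- pairs[is.finite(vals), , drop = FALSE]
  }
  binary_from_pairs(colnames(x), pairs)
}
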