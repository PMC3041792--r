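# Select the top-k unordered pairs of a symmetric score matrix.
# Tie rule everywhere in the package: descending value, then lexicographic
# (gene_i, gene_j) with gene_i < gene_j — bit-identical outputs across runs.
# Returns a two-column index matrix (upper-triangle indices, i < j by
# universe order).
select_top_pairs <- function(m, k, include_self = FALSE) {
  genes <- rownames(m)
  ut <- upper.tri(m, diag = include_self)
  idx <- which(ut, arr.ind = TRUE)
  val <- m[ut]
  eligible <- is.finite(val) & val > 0     # zero-scored pairs never edges
  idx <- idx[eligible, , drop = FALSE]
  val <- val[eligible]
  gi <- genes[idx[, 1]]
  gj <- genes[idx[, 2]]
  a <- pmin(gi, gj)
  b <- pmax(gi, gj)
  ord <- order(-val, a, b)
  k <- min(k, length(ord))
  if (k <= 0) return(idx[0, , drop = FALSE])
  idx[ord[seq_len(k)], , drop = FALSE]
}

# Build a binary network from selected upper-triangle index pairs.
binary_from_pairs <- function(genes, pairs) {
  m <- matrix(0, length(genes), length(genes), dimnames = list(genes, genes))
  if (nrow(pairs) > 0) {
    keep <- pairs[, 1] != pairs[, 2]
    p <- pairs[keep, , drop = FALSE]
    m[p] <- 1
    m[p[, c(2, 1), drop = FALSE]] <- 1
  }
  as_network(m, binary = TRUE)
}

#' Global-threshold sparsification
#'
#' Keeps the top `sparsity` fraction of all off-diagonal unordered pairs by
#' value (a single global threshold) and binarizes. The default 0.5% is the
#' conventional density for thresholded coexpression networks.
#'
#' @param m A symmetric numeric matrix with gene dimnames, or a
#'   `gba_network` (its weights are used).
#' @param sparsity Fraction of unordered pairs to keep, in (0, 1).
#' @return A binary `gba_network` with `floor(sparsity * n_pairs)` edges
#'   (ties at the threshold resolved deterministically: descending value,
#'   then lexicographic pair).
#' @export
threshold_sparsify <- function(m, sparsity = 0.005) {
  m <- as_weight_matrix(m)
  if (sparsity <= 0 || sparsity >= 1) abort("`sparsity` must be in (0, 1).")
  ng <- nrow(m)
  k <- floor(sparsity * ng * (ng - 1) / 2)
  binary_from_pairs(rownames(m), select_top_pairs(m, k))
}

#' Top-overlap (mutual top partner) sparsification
#'
#' For each gene a per-gene threshold keeps its top `per_gene_sparsity`
#' fraction of partners; an edge survives only if each endpoint is in the
#' other's top set (mutual nearest-neighbor rule). Compared to a global
#' threshold this compresses the node-degree range — but note it largely
#' preserves node-degree *ranks*, so it does not remove multifunctionality
#' bias.
#'
#' @param m Symmetric matrix or `gba_network`.
#' @param per_gene_sparsity Per-gene fraction of partners to keep. A gene
#'   whose top list would be shorter than one partner contributes no edges.
#' @return A binary `gba_network`.
#' @export
top_overlap_sparsify <- function(m, per_gene_sparsity = 0.005) {
  m <- as_weight_matrix(m)
  if (per_gene_sparsity <= 0 || per_gene_sparsity >= 1) {
    abort("`per_gene_sparsity` must be in (0, 1).")
  }
  ng <- nrow(m)
  genes <- rownames(m)
  t_n <- floor(per_gene_sparsity * (ng - 1))
  keep <- matrix(FALSE, ng, ng, dimnames = dimnames(m))
  if (t_n >= 1) {
    for (i in seq_len(ng)) {
      v <- m[i, ]
      v[i] <- -Inf
      ord <- order(-v, genes)   # ties: lexicographic partner id
      top <- ord[seq_len(t_n)]
      keep[i, top[v[top] > 0]] <- TRUE   # zero associations never edges
    }
  }
  mutual <- keep & t(keep)
  diag(mutual) <- FALSE
  as_network(matrix(as.numeric(mutual), ng, ng, dimnames = dimnames(m)),
             binary = TRUE)
}

#' Aggregate networks
#'
#' `mode = "sum"` adds the weight matrices (for binary inputs the result
#' counts supporting networks per edge, the construction used for summed
#' coexpression matrices); `mode = "union"` keeps a binary edge wherever any
#' input has one.
#'
#' @param nets List of `gba_network` objects on the same universe, or
#'   universes whose union is used (missing genes zero-filled, with a
#'   message).
#' @param mode `"sum"` or `"union"`.
#' @return A `gba_network`.
#' @export
aggregate_networks <- function(nets, mode = c("sum", "union")) {
  mode <- match.arg(mode)
  if (length(nets) == 0) abort("`nets` must not be empty.")
  stopifnot(all(vapply(nets, inherits, TRUE, "gba_network")))
  unis <- lapply(nets, function(n) rownames(n$weights))
  uni <- unis[[1]]
  if (!all(vapply(unis, identical, TRUE, uni))) {
    uni <- sort(unique(unlist(unis)))
    inform("aggregate_networks: universes differ; using their union with zero fill.")
  }
  acc <- matrix(0, length(uni), length(uni), dimnames = list(uni, uni))
  for (n in nets) {
    g <- rownames(n$weights)
    acc[g, g] <- acc[g, g] + n$weights
  }
  if (mode == "union") {
    acc <- matrix(as.numeric(acc != 0), length(uni), length(uni),
                  dimnames = list(uni, uni))
  }
  as_network(acc, binary = (mode == "union"))
}

# Accept either a gba_network or a raw symmetric matrix.
as_weight_matrix <- function(m) {
  if (inherits(m, "gba_network")) return(m$weights)
  if (!is.matrix(m)) abort("Expected a matrix or gba_network.")
  if (is.null(rownames(m))) abort("Matrix must have gene dimnames.")
  if (!isSymmetric(unname(m), tol = 1e-10)) abort("Matrix must be symmetric.")
  m
}
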