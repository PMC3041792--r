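#' Construct a gene association network
#'
#' A network is a symmetric, non-negative gene-by-gene weight matrix with a
#' zero diagonal (self-association is handled only inside IPN sparsity
#' accounting). Binary networks are weight matrices restricted to \{0, 1\}.
#'
#' @param weights Symmetric numeric matrix with matching, unique row/column
#'   gene names. The diagonal is forced to zero.
#' @param binary Logical; if `NULL` (default), inferred from the weights.
#' @return An object of class `gba_network`: a list with elements `weights`
#'   (the matrix) and `binary`.
#' @export
as_network <- function(weights, binary = NULL) {
  if (!is.matrix(weights)) abort("`weights` must be a matrix.")
  if (nrow(weights) != ncol(weights)) abort("`weights` must be square.")
  if (is.null(rownames(weights)) ||
      !identical(rownames(weights), colnames(weights))) {
    abort("`weights` must have identical row and column gene names.")
  }
  if (anyDuplicated(rownames(weights))) abort("Duplicate gene ids.")
  if (anyNA(weights)) abort("`weights` must not contain NA.")
  if (!isSymmetric(unname(weights), tol = 1e-10)) {
    abort("`weights` must be symmetric.")
  }
  if (any(weights < 0)) abort("`weights` must be non-negative.")
  diag(weights) <- 0
  if (is.null(binary)) binary <- all(weights %in% c(0, 1))
  structure(list(weights = weights, binary = binary), class = "gba_network")
}

#' Build a network from an edge list
#'
#' @param edges Data frame with columns `gene_i`, `gene_j` and optionally
#'   `weight` (default 1). Edges are undirected; duplicate pairs are summed.
#' @param universe Optional character vector of gene ids (supplies isolated
#'   genes and fixes order); defaults to the sorted union of endpoint genes.
#' @return A `gba_network`.
#' @export
network_from_edges <- function(edges, universe = NULL) {
  edges <- as.data.frame(edges)
  if (!all(c("gene_i", "gene_j") %in% names(edges))) {
    abort("`edges` needs columns `gene_i` and `gene_j`.")
  }
  w <- if ("weight" %in% names(edges)) as.numeric(edges$weight) else
    rep(1, nrow(edges))
  gi <- as.character(edges$gene_i)
  gj <- as.character(edges$gene_j)
  if (any(gi == gj)) abort("Self-edges are not allowed.")
  uni <- universe %||% sort(unique(c(gi, gj)))
  if (!all(c(gi, gj) %in% uni)) {
    abort("Edge endpoints outside the supplied universe.")
  }
  m <- matrix(0, length(uni), length(uni), dimnames = list(uni, uni))
  ii <- match(gi, uni); jj <- match(gj, uni)
  for (k in seq_along(ii)) {
    m[ii[k], jj[k]] <- m[ii[k], jj[k]] + w[k]
    m[jj[k], ii[k]] <- m[jj[k], ii[k]] + w[k]
  }
  as_network(m)
}

#' @export
print.gba_network <- function(x, ...) {
  cat(sprintf("<gba_network> %d genes, %d edges (sparsity %.4g)%s\n",
              nrow(x$weights), network_edge_count(x), network_sparsity(x),
              if (x$binary) ", binary" else ", weighted"))
  invisible(x)
}

#' Edge count and sparsity of a network
#'
#' Sparsity is the fraction of the `n (n - 1) / 2` unordered gene pairs that
#' carry a nonzero weight.
#'
#' @param n A `gba_network`.
#' @return A single number.
#' @export
network_sparsity <- function(n) {
  stopifnot(inherits(n, "gba_network"))
  ng <- nrow(n$weights)
  network_edge_count(n) / (ng * (ng - 1) / 2)
}

#' @rdname network_sparsity
#' @export
network_edge_count <- function(n) {
  stopifnot(inherits(n, "gba_network"))
  sum(n$weights[upper.tri(n$weights)] != 0)
}

#' Weighted node degree
#'
#' The degree of a gene is the row sum of the association matrix — for a
#' binary network, the number of connections. Under a prevalence model in
#' which genes interact with probability proportional to the product of
#' per-gene propensities, this row sum recovers the propensity ranking, which
#' is why node degree alone can predict gene function when annotations are
#' coupled to prevalence.
#'
#' @param n A `gba_network`.
#' @return A tibble `gene`, `degree`, in universe order.
#' @export
node_degree <- function(n) {
  stopifnot(inherits(n, "gba_network"))
  tibble::tibble(gene = rownames(n$weights),
                 degree = unname(rowSums(n$weights)))
}

#' Fixed gene ranking by node degree
#'
#' @param n A `gba_network`.
#' @param tie_policy Passed to [gene_ranking()].
#' @return A [gene_ranking()] scored by weighted node degree.
#' @export
degree_ranking <- function(n, tie_policy = c("average", "stable")) {
  d <- node_degree(n)
  gene_ranking(stats::setNames(d$degree, d$gene), match.arg(tie_policy))
}

#' Extract the edge list of a network
#'
#' @param n A `gba_network`.
#' @return Tibble `gene_i`, `gene_j`, `weight`, with `gene_i < gene_j`
#'   lexicographically and rows sorted by (`gene_i`, `gene_j`).
#' @export
network_edges <- function(n) {
  stopifnot(inherits(n, "gba_network"))
  w <- n$weights
  idx <- which(upper.tri(w) & w != 0, arr.ind = TRUE)
  gi <- rownames(w)[idx[, 1]]
  gj <- colnames(w)[idx[, 2]]
  swap <- gi > gj
  tmp <- gi[swap]; gi[swap] <- gj[swap]; gj[swap] <- tmp
  out <- tibble::tibble(gene_i = gi, gene_j = gj,
                        weight = w[idx])
  dplyr::arrange(out, .data$gene_i, .data$gene_j)
}

#' Read / write networks as TSV edge lists
#'
#' The edge-list format is tab-separated `gene_i`, `gene_j`, `weight` with a
#' header row.
#'
#' @param path File path.
#' @param universe Optional gene universe (see [network_from_edges()]).
#' @param n A `gba_network`.
#' @return `read_edge_list()` a `gba_network`; `write_edge_list()` `path`,
#'   invisibly.
#' @export
read_edge_list <- function(path, universe = NULL) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  if (ncol(d) < 2) abort("Edge list needs at least two columns.")
  names(d)[1:2] <- c("gene_i", "gene_j")
  if (ncol(d) >= 3) names(d)[3] <- "weight"
  network_from_edges(d, universe = universe)
}

#' @rdname read_edge_list
#' @export
write_edge_list <- function(n, path) {
  readr::write_tsv(network_edges(n), path)
  invisible(path)
}

#' Read a symmetric network from a dense TSV matrix or MatrixMarket file
#'
#' @param path File path. For `read_network_matrix()`, a TSV whose first
#'   column holds gene ids and whose header names the same genes. For
#'   `read_network_mtx()`, a MatrixMarket coordinate file.
#' @param genes For MTX input, character vector naming the rows (MTX carries
#'   no identifiers).
#' @return A `gba_network`.
#' @export
read_network_matrix <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  genes <- as.character(d[[1]])
  m <- as.matrix(d[-1])
  rownames(m) <- genes
  colnames(m) <- names(d)[-1]
  as_network(m[, genes, drop = FALSE])
}

#' @rdname read_network_matrix
#' @export
read_network_mtx <- function(path, genes) {
  m <- as.matrix(Matrix::readMM(path))
  if (nrow(m) != length(genes)) {
    abort("`genes` length must match the MTX dimension.")
  }
  m <- pmax(m, t(m))      # tolerate one-triangle general storage
  dimnames(m) <- list(genes, genes)
  diag(m) <- 0
  as_network(m)
}

#' Align a network and an annotation matrix on a common universe
#'
#' Re-bases both objects on the sorted union of their gene universes:
#' genes absent from the network become isolated nodes, genes absent from
#' the annotations become unannotated negatives (which is what preserves
#' multifunctionality control strength — dropping them weakens every
#' comparison).
#'
#' @param n A `gba_network`.
#' @param a An [annotation_matrix()].
#' @return A list with elements `network` and `annotations` on the shared
#'   universe.
#' @export
align_universe <- function(n, a) {
  stopifnot(inherits(n, "gba_network"), inherits(a, "annotation_matrix"))
  uni <- sort(union(rownames(n$weights), rownames(a)))
  w <- matrix(0, length(uni), length(uni), dimnames = list(uni, uni))
  g <- rownames(n$weights)
  w[g, g] <- n$weights
  list(network = as_network(w, binary = n$binary),
       annotations = annotation_matrix(unclass(a), universe = uni))
}

# Internal: check two objects share a gene universe.
check_shared_universe <- function(n, a) {
  if (!identical(rownames(n$weights), rownames(a))) {
    abort("Network and annotations must share the same gene universe (same ids, same order).")
  }
  invisible(TRUE)
}
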