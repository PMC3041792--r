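#' Construct a binary gene-by-group annotation matrix
#'
#' The annotation matrix is the package's representation of a gene-set
#' collection: a logical matrix with one row per gene in the universe and one
#' column per function group (GO term, KEGG pathway, disease gene set, ...).
#' Genes not annotated to any group stay in the universe as negatives; this
#' matters because dropping them weakens every multifunctionality control.
#'
#' @param membership Logical (or 0/1) matrix, genes in rows, groups in columns.
#'   Row and column names are required and must be unique.
#' @param universe Optional character vector fixing the gene universe and its
#'   order. Genes of `membership` absent from it are dropped (with a message);
#'   universe genes absent from `membership` become all-`FALSE` rows.
#'
#' @return An object of class `annotation_matrix`: a logical matrix with
#'   unique `rownames` (the gene universe, order preserved) and `colnames`
#'   (the group ids).
#' @examples
#' m <- matrix(c(TRUE, TRUE, FALSE), 3, 1,
#'             dimnames = list(c("g1", "g2", "g3"), "S1"))
#' a <- annotation_matrix(m)
#' group_sizes(a)
#' @export
annotation_matrix <- function(membership, universe = NULL) {
  if (!is.matrix(membership)) {
    abort("`membership` must be a matrix.")
  }
  if (is.null(rownames(membership)) ||
      (ncol(membership) > 0 && is.null(colnames(membership)))) {
    abort("`membership` must have gene rownames and group colnames.")
  }
  if (anyDuplicated(rownames(membership))) {
    abort("Duplicate gene ids in `membership` rows.")
  }
  if (anyDuplicated(colnames(membership))) {
    abort("Duplicate group ids in `membership` columns.")
  }
  storage.mode(membership) <- "logical"
  if (anyNA(membership)) abort("`membership` must not contain NA.")
  if (!is.null(universe)) {
    universe <- as.character(universe)
    if (anyDuplicated(universe)) abort("`universe` ids must be unique.")
    dropped <- setdiff(rownames(membership), universe)
    if (length(dropped) > 0) {
      inform(sprintf("Dropping %d gene(s) absent from the supplied universe.",
                     length(dropped)))
    }
    out <- matrix(FALSE, length(universe), ncol(membership),
                  dimnames = list(universe, colnames(membership)))
    keep <- intersect(rownames(membership), universe)
    out[keep, ] <- membership[keep, , drop = FALSE]
    membership <- out
  }
  if (nrow(membership) == 0) abort("Empty gene universe.")
  structure(membership, class = c("annotation_matrix", "matrix", "array"))
}

#' @export
print.annotation_matrix <- function(x, ...) {
  cat(sprintf(
    "<annotation_matrix> %d genes x %d groups (%d memberships)\n",
    nrow(x), ncol(x), sum(x)
  ))
  if (ncol(x) > 0) {
    sz <- group_sizes(x)
    cat(sprintf("  group sizes: min %d, median %s, max %d\n",
                min(sz), format(stats::median(sz)), max(sz)))
  }
  invisible(x)
}

#' Universe, group sizes and complements of an annotation matrix
#'
#' `group_sizes()` returns the number of annotated genes per group
#' (the in-group count used by the multifunctionality weighting) and
#' `complement_sizes()` the number of universe genes outside each group.
#'
#' @param a An [annotation_matrix()].
#' @return Named integer vector, one entry per group; `gene_universe()`
#'   returns the ordered character vector of gene ids.
#' @export
group_sizes <- function(a) {
  stopifnot(inherits(a, "annotation_matrix"))
  colSums(unclass(a))
}

#' @rdname group_sizes
#' @export
complement_sizes <- function(a) {
  nrow(a) - group_sizes(a)
}

#' @rdname group_sizes
#' @export
gene_universe <- function(a) {
  if (inherits(a, "annotation_matrix")) return(rownames(a))
  if (inherits(a, "gba_network")) return(rownames(a$weights))
  abort("No gene universe defined for this object.")
}

#' Filter annotation groups by size
#'
#' Keeps exactly the groups whose gene count lies in `[min_size, max_size]`;
#' the gene universe is unchanged. The conventional window for GO-style
#' evaluations is 20-1000 genes: smaller groups are statistically unstable,
#' larger ones uninformatively broad.
#'
#' @param a An [annotation_matrix()].
#' @param min_size,max_size Inclusive bounds on group size.
#' @return An [annotation_matrix()] with the retained groups, original order.
#' @examples
#' a <- annotation_matrix(matrix(
#'   c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE), 3, 2,
#'   dimnames = list(c("g1", "g2", "g3"), c("S1", "S2"))
#' ))
#' filter_by_size(a, min_size = 3, max_size = 3)
#' @export
filter_by_size <- function(a, min_size = 20, max_size = 1000) {
  stopifnot(inherits(a, "annotation_matrix"))
  if (min_size < 1) abort("`min_size` must be >= 1.")
  if (min_size > max_size) abort("`min_size` must not exceed `max_size`.")
  sz <- group_sizes(a)
  keep <- sz >= min_size & sz <= max_size
  if (!any(keep)) {
    warn("All groups removed by the size filter.")
  }
  annotation_matrix(unclass(a)[, keep, drop = FALSE])
}

#' Summarise an annotation matrix as a tibble
#'
#' @param x An [annotation_matrix()].
#' @param ... Unused.
#' @return A tibble with one row per group: `group`, `size`,
#'   `complement_size`.
#' @export
tidy.annotation_matrix <- function(x, ...) {
  tibble::tibble(
    group = colnames(x),
    size = unname(group_sizes(x)),
    complement_size = unname(complement_sizes(x))
  )
}
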