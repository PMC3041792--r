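#' Build a gene ranking from per-gene scores
#'
#' A gene ranking is a total order over a gene universe by decreasing score.
#' Under the `"average"` tie policy, tied genes share the mean of the
#' positions they span (midranks), which is what every downstream metric
#' uses; `"stable"` breaks ties by input order and yields a strict
#' permutation for exact reproducibility of emitted lists.
#'
#' @param score Named numeric vector: one finite score per gene; higher means
#'   ranked earlier (better candidate).
#' @param tie_policy `"average"` (default) or `"stable"`.
#' @return A tibble of class `gene_ranking` with columns `gene`, `score`,
#'   `rank` (1 = top), ordered by rank; the tie policy is kept as an
#'   attribute.
#' @export
gene_ranking <- function(score, tie_policy = c("average", "stable")) {
  tie_policy <- match.arg(tie_policy)
  if (is.null(names(score)) || anyDuplicated(names(score))) {
    abort("`score` must be named with unique gene ids.")
  }
  if (anyNA(score) || any(!is.finite(score))) {
    abort("Scores must be finite.")
  }
  rk <- switch(tie_policy,
    average = rank(-score, ties.method = "average"),
    stable = rank(-score, ties.method = "first")
  )
  out <- tibble::tibble(gene = names(score), score = unname(score),
                        rank = unname(rk))
  out <- dplyr::arrange(out, .data$rank, .data$gene)
  structure(out, class = c("gene_ranking", class(tibble::tibble())),
            tie_policy = tie_policy)
}

#' @export
print.gene_ranking <- function(x, ...) {
  cat(sprintf("<gene_ranking> %d genes, tie policy '%s'\n",
              nrow(x), attr(x, "tie_policy")))
  NextMethod()
}

# Named score vector aligned to `universe` for metric evaluation.
ranking_scores <- function(r, universe = NULL) {
  stopifnot(inherits(r, "gene_ranking"))
  s <- stats::setNames(r$score, r$gene)
  if (is.null(universe)) return(s)
  missing <- setdiff(universe, names(s))
  if (length(missing) > 0) {
    abort(sprintf("Ranking does not cover %d universe gene(s), e.g. %s.",
                  length(missing), missing[1]))
  }
  s[universe]
}

#' Read / write a gene ranking as TSV
#'
#' Plain three-column TSV (`gene`, `score`, `rank`), ordered by rank.
#'
#' @param r A [gene_ranking()].
#' @param path File path.
#' @param tie_policy Tie policy used to rebuild the ranking on read.
#' @return `write_ranking()` returns `path` invisibly; `read_ranking()`
#'   returns a [gene_ranking()].
#' @export
write_ranking <- function(r, path) {
  stopifnot(inherits(r, "gene_ranking"))
  readr::write_tsv(as.data.frame(r), path)
  invisible(path)
}

#' @rdname write_ranking
#' @export
read_ranking <- function(path, tie_policy = c("average", "stable")) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("gene", "score") %in% names(d))) {
    abort("Ranking TSV must have columns `gene` and `score`.")
  }
  gene_ranking(stats::setNames(d$score, d$gene), match.arg(tie_policy))
}
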