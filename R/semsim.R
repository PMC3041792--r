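# --- Annotation semantic similarity of network links ----------------------

similarity_measures <- c("dice", "jaccard", "overlap_count", "half_dice")

# Vectorized pair similarity for index vectors i, j (equal length).
pair_similarity_idx <- function(m, i, j, measure) {
  inter <- rowSums(m[i, , drop = FALSE] & m[j, , drop = FALSE])
  ni <- rowSums(m[i, , drop = FALSE])
  nj <- rowSums(m[j, , drop = FALSE])
  out <- switch(measure,
    overlap_count = inter,
    dice = ifelse(ni + nj == 0, 0, 2 * inter / (ni + nj)),
    half_dice = ifelse(ni + nj == 0, 0, inter / (ni + nj)),
    jaccard = {
      un <- ni + nj - inter
      ifelse(un == 0, 0, inter / un)
    },
    abort(sprintf("Unknown measure: %s", measure))
  )
  as.numeric(out)
}

#' Annotation overlap similarity of a gene pair
#'
#' Similarity of the two genes' annotation term sets: `overlap_count` is the
#' raw number of shared groups; `dice` is `2|T1 n T2| / (|T1| + |T2|)`;
#' `jaccard` is `|T1 n T2| / |T1 u T2|`; `half_dice` is the overlap
#' normalized by the plain sum of the two term counts (maximum 0.5). All
#' measures return 0 when either gene has no annotations.
#'
#' @param a An [annotation_matrix()].
#' @param g1,g2 Gene ids in the universe of `a`.
#' @param measure One of `"dice"` (default), `"jaccard"`, `"overlap_count"`,
#'   `"half_dice"`.
#' @return A single number.
#' @export
pair_similarity <- function(a, g1, g2,
                            measure = c("dice", "jaccard", "overlap_count",
                                        "half_dice")) {
  stopifnot(inherits(a, "annotation_matrix"))
  measure <- match.arg(measure)
  uni <- rownames(a)
  if (!g1 %in% uni || !g2 %in% uni) abort("Unknown gene id.")
  pair_similarity_idx(unclass(a), match(g1, uni), match(g2, uni), measure)
}

#' Mean annotation similarity of network links, with a random baseline
#'
#' Scores every edge of the network by the annotation-set similarity of its
#' endpoints and compares the mean against the mean over randomly sampled
#' gene pairs (with replacement, self-pairs excluded, same measure). No
#' learning step is involved, so this audits the network itself: links in a
#' functionally meaningful network should be more similar than random —
#' but so are links of an IPN, which is the point of the comparison.
#'
#' @param n A `gba_network`.
#' @param a An [annotation_matrix()] on the same universe.
#' @param measure See [pair_similarity()].
#' @param baseline_replicates Number of random pairs for the baseline
#'   (default `10000`).
#' @param seed Integer seed for the baseline sampling.
#' @return A tibble of class `link_similarity` with one row per edge
#'   (`gene_i`, `gene_j`, `similarity`); the mean, baseline mean, measure
#'   and replicate count are attributes, surfaced by [glance()].
#' @export
network_similarity <- function(n, a,
                               measure = c("dice", "jaccard",
                                           "overlap_count", "half_dice"),
                               baseline_replicates = 10000, seed = 1) {
  stopifnot(inherits(n, "gba_network"), inherits(a, "annotation_matrix"))
  check_shared_universe(n, a)
  measure <- match.arg(measure)
  edges <- network_edges(n)
  if (nrow(edges) == 0) abort("Empty network.")
  uni <- rownames(a)
  m <- unclass(a)
  sim <- pair_similarity_idx(m, match(edges$gene_i, uni),
                             match(edges$gene_j, uni), measure)
  set.seed(seed)
  ng <- length(uni)
  bi <- sample.int(ng, baseline_replicates, replace = TRUE)
  bj <- sample.int(ng - 1, baseline_replicates, replace = TRUE)
  bj <- ifelse(bj >= bi, bj + 1L, bj)      # uniform over j != i
  baseline <- pair_similarity_idx(m, bi, bj, measure)
  out <- tibble::tibble(gene_i = edges$gene_i, gene_j = edges$gene_j,
                        similarity = sim)
  structure(out, class = c("link_similarity", class(tibble::tibble())),
            measure = measure, mean = mean(sim),
            baseline_mean = mean(baseline),
            baseline_replicates = baseline_replicates, seed = seed)
}

#' @export
print.link_similarity <- function(x, ...) {
  cat(sprintf(
    "<link_similarity> %d links, measure '%s': mean %.4f vs random %.4f\n",
    nrow(x), attr(x, "measure"), attr(x, "mean"),
    attr(x, "baseline_mean")))
  NextMethod()
}

#' @export
glance.link_similarity <- function(x, ...) {
  tibble::tibble(
    measure = attr(x, "measure"),
    n_links = nrow(x),
    mean_similarity = attr(x, "mean"),
    baseline_mean = attr(x, "baseline_mean"),
    baseline_replicates = attr(x, "baseline_replicates")
  )
}

#' @export
tidy.link_similarity <- function(x, ...) tibble::as_tibble(x)

#' Histogram of per-link annotation similarity
#'
#' Bins the per-link similarity values of a network, for comparing the
#' similarity profiles of a real network, its IPN, and random links.
#'
#' @param n A `gba_network`.
#' @param a An [annotation_matrix()] on the same universe.
#' @param measure See [pair_similarity()].
#' @param bin_width Histogram bin width (default 0.05; for
#'   `"overlap_count"`, 1).
#' @return A tibble `bin_lower`, `bin_upper`, `count`; counts sum to the
#'   edge count.
#' @export
similarity_distribution <- function(n, a,
                                    measure = c("dice", "jaccard",
                                                "overlap_count",
                                                "half_dice"),
                                    bin_width = NULL) {
  measure <- match.arg(measure)
  ls <- network_similarity(n, a, measure = measure, baseline_replicates = 1)
  bin_width <- bin_width %||% if (measure == "overlap_count") 1 else 0.05
  top <- max(ls$similarity, bin_width)
  breaks <- seq(0, bin_width * ceiling(top / bin_width + 1e-9), bin_width)
  h <- graphics::hist(ls$similarity, breaks = breaks, plot = FALSE,
                      right = FALSE, include.lowest = TRUE)
  tibble::tibble(bin_lower = h$breaks[-length(h$breaks)],
                 bin_upper = h$breaks[-1],
                 count = h$counts)
}
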