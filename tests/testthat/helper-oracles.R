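# Independent brute-force oracles and fixture builders used across the
# suite. These deliberately avoid the package's own code paths: metrics are
# recomputed by direct pair/precision enumeration, selections by explicit
# sorting.

# -- metric oracles ---------------------------------------------------------

# AUROC by explicit enumeration of all (positive, negative) pairs.
oracle_auc <- function(labels, scores) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# Truncated ROC by pair enumeration restricted to the n_fp highest-scoring
# negatives.
oracle_roc50 <- function(labels, scores, n_fp = 50) {
  pos <- scores[as.logical(labels)]
  neg <- sort(scores[!as.logical(labels)], decreasing = TRUE)
  m <- min(n_fp, length(neg))
  neg <- neg[seq_len(m)]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  sum(cmp) / (m * length(pos))
}

# PPV@k with expected true positives under random tie resolution, computed
# from first principles.
oracle_ppv <- function(labels, scores, k) {
  labels <- as.logical(labels)
  vals <- sort(unique(scores), decreasing = TRUE)
  tp <- 0
  slots <- k
  for (v in vals) {
    in_block <- scores == v
    take <- min(slots, sum(in_block))
    tp <- tp + take * sum(labels[in_block]) / sum(in_block)
    slots <- slots - take
    if (slots == 0) break
  }
  tp / k
}

# Average precision by direct cumulative-precision summation (stable ties).
oracle_aup <- function(labels, scores) {
  labels <- as.logical(labels)[order(-scores)]
  hits <- 0
  out <- numeric(0)
  for (i in seq_along(labels)) {
    if (labels[i]) {
      hits <- hits + 1
      out <- c(out, hits / i)
    }
  }
  mean(out)
}

# -- combinatorics ----------------------------------------------------------

# All permutations of a vector (n! rows).
all_permutations <- function(v) {
  n <- length(v)
  if (n == 1) return(matrix(v, 1, 1))
  out <- NULL
  for (i in seq_len(n)) {
    sub <- all_permutations(v[-i])
    out <- rbind(out, cbind(v[i], sub))
  }
  out
}

# -- fixture builders -------------------------------------------------------

gene_ids <- function(n) sprintf("g%02d", seq_len(n))

# Random annotation matrix with guaranteed non-degenerate groups.
random_annotation <- function(n_genes, n_groups, seed,
                              min_size = 1, max_size = n_genes - 1) {
  set.seed(seed)
  genes <- gene_ids(n_genes)
  m <- matrix(FALSE, n_genes, n_groups,
              dimnames = list(genes, sprintf("S%02d", seq_len(n_groups))))
  for (j in seq_len(n_groups)) {
    s <- sample(min_size:max_size, 1)
    m[sample(n_genes, s), j] <- TRUE
  }
  annotation_matrix(m)
}

# Random symmetric non-negative weight matrix, zero diagonal.
random_symmetric <- function(n, seed) {
  set.seed(seed)
  m <- matrix(runif(n * n), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dimnames(m) <- list(gene_ids(n), gene_ids(n))
  m
}

# A planted-clique fixture on a uniform-degree background: `n_genes` genes,
# one group whose members form a clique; background edges Erdos-Renyi.
planted_clique_fixture <- function(n_genes = 60, clique_size = 12,
                                   background = 0.02, seed = 1) {
  set.seed(seed)
  genes <- gene_ids(n_genes)
  w <- matrix(as.numeric(matrix(runif(n_genes^2), n_genes) < background),
              n_genes, n_genes, dimnames = list(genes, genes))
  w[lower.tri(w)] <- t(w)[lower.tri(w)]
  members <- genes[seq_len(clique_size)]
  w[members, members] <- 1
  diag(w) <- 0
  net <- as_network(w, binary = TRUE)
  a <- annotation_matrix(matrix(genes %in% members, ncol = 1,
                                dimnames = list(genes, "clique")))
  list(net = net, annot = a, members = members)
}

# Write a temporary GMT file from a list of character vectors.
write_tmp_gmt <- function(sets, descriptions = NULL) {
  path <- withr::local_tempfile(fileext = ".gmt",
                                .local_envir = parent.frame())
  desc <- descriptions %||% rep(".", length(sets))
  lines <- mapply(function(nm, d, genes) paste(c(nm, d, genes),
                                               collapse = "\t"),
                  names(sets), desc, sets)
  writeLines(lines, path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a
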