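annot_from_sets <- function(universe, sets) {
  m <- matrix(FALSE, length(universe), length(sets),
              dimnames = list(universe, names(sets)))
  for (j in seq_along(sets)) m[sets[[j]], j] <- TRUE
  annotation_matrix(m)
}

test_that("multifunctionality scores follow the 1/(n_in * n_out) weighting", {
  a <- annot_from_sets(c("g1", "g2", "g3"), list(A = "g1"))
  mf <- multifunctionality_scores(a)
  expect_equal(mf$score, c(0.5, 0, 0))       # 1/(1*2)

  a2 <- annot_from_sets(c("g1", "g2", "g3"), list(A = "g1", B = "g1"))
  expect_equal(multifunctionality_scores(a2)$score[1], 1.0)  # additive

  a3 <- annot_from_sets(gene_ids(10), list(A = gene_ids(4)))
  mf3 <- multifunctionality_scores(a3)
  expect_equal(mf3$score[1:4], rep(1 / 24, 4))
  expect_equal(mf3$score[5:10], rep(0, 6))
})

test_that("every member of a group of size s contributes exactly 1/(s(N-s))", {
  a <- random_annotation(20, 6, seed = 4, min_size = 2, max_size = 15)
  mf <- multifunctionality_scores(a)
  n <- nrow(a)
  expected <- sapply(seq_len(n), function(g) {
    sum(sapply(which(unclass(a)[g, ]), function(j) {
      s <- sum(a[, j]); 1 / (s * (n - s))
    }))
  })
  expect_equal(mf$score, unname(expected))
})

test_that("adding a membership never decreases a gene's score or moves others", {
  a <- random_annotation(15, 4, seed = 8, min_size = 2, max_size = 10)
  mf0 <- multifunctionality_scores(a)
  m <- unclass(a)
  g <- which(!m[, 2])[1]
  m2 <- m
  m2[g, 2] <- TRUE
  mf1 <- multifunctionality_scores(annotation_matrix(m2))
  expect_gt(mf1$score[g], mf0$score[g])
  # other genes' contributions change only through group 2's size shift;
  # removing group 2 from both, all other genes are untouched
  mf0_rest <- multifunctionality_scores(annotation_matrix(m[, -2, drop = FALSE]))
  mf1_rest <- multifunctionality_scores(annotation_matrix(m2[, -2, drop = FALSE]))
  expect_equal(mf0_rest$score, mf1_rest$score)
})

test_that("groups spanning the whole universe are excluded with a warning", {
  m <- matrix(TRUE, 4, 1, dimnames = list(gene_ids(4), "ALL"))
  expect_warning(mf <- multifunctionality_scores(annotation_matrix(m)),
                 "excluded")
  expect_equal(mf$score, rep(0, 4))
})

test_that("the optimal ranking is the multifunctionality order, unannotated last", {
  a <- annot_from_sets(c("g1", "g2", "g3"), list(A = "g1"))
  r <- optimal_ranking_auc(a)
  expect_equal(r$gene[1], "g1")
  expect_equal(r$rank[2:3], c(2.5, 2.5))     # unannotated tied last

  # identical annotations for everyone leave all genes tied (whole-universe
  # groups are excluded from scoring), and an all-tied ranking scores 0.5
  # against any group by the average-tie convention
  m <- matrix(TRUE, 4, 2, dimnames = list(gene_ids(4), c("A", "B")))
  suppressWarnings(tied <- optimal_ranking_auc(annotation_matrix(m)))
  expect_equal(unique(tied$rank), 2.5)
  probe <- annot_from_sets(gene_ids(4), list(P = c("g01", "g03")))
  expect_equal(evaluate_fixed_ranking(tied, probe)$value, 0.5)
})

test_that("no fixed permutation beats the optimal ranking on small instances", {
  for (seed in 1:8) {
    n <- sample(4:6, 1)
    a <- random_annotation(n, sample(2:4, 1), seed = 100 + seed,
                           min_size = 1, max_size = n - 1)
    opt <- optimal_ranking_auc(a)
    opt_mean <- mean(evaluate_fixed_ranking(opt, a)$value)
    perms <- all_permutations(seq_len(n))
    best <- max(apply(perms, 1, function(p) {
      scores <- numeric(n)
      scores[p] <- n:1
      mean(sapply(colnames(a), function(g) oracle_auc(a[, g], scores)))
    }))
    expect_gte(opt_mean + 1e-12, best)
  }
})

test_that("PPV-optimal ranking matches brute force and degenerates sensibly", {
  # single group: members first, like the AUC-optimal order
  a1 <- annot_from_sets(gene_ids(5), list(A = c("g02", "g04")))
  r1 <- optimal_ranking_ppv(a1, k = 2)
  expect_setequal(r1$gene[1:2], c("g02", "g04"))

  # brute force over all orderings on small instances: greedy attains the
  # maximal mean PPV@k
  for (seed in 1:5) {
    n <- 6
    a <- random_annotation(n, 3, seed = 200 + seed, min_size = 1,
                           max_size = n - 1)
    k <- 3
    r <- optimal_ranking_ppv(a, k = k)
    mine <- mean(sapply(colnames(a), function(g)
      oracle_ppv(a[, g], stats::setNames(r$score, r$gene)[rownames(a)], k)))
    perms <- all_permutations(seq_len(n))
    best <- max(apply(perms, 1, function(p) {
      scores <- numeric(n)
      scores[p] <- n:1
      mean(sapply(colnames(a), function(g) oracle_ppv(a[, g], scores, k)))
    }))
    expect_equal(mine, best, tolerance = 1e-12)
  }

  # k = |universe|: every ordering gives the same PPV; call must succeed
  r_full <- optimal_ranking_ppv(a1, k = 5)
  expect_equal(sort(r_full$gene), sort(rownames(a1)))
  expect_error(optimal_ranking_ppv(a1, k = 6), "universe")
})

test_that("group multifunctionality table matches per-group AUC recomputation", {
  a <- random_annotation(30, 10, seed = 5, min_size = 3, max_size = 20)
  r <- optimal_ranking_auc(a)
  tbl <- group_multifunctionality(a, r)
  sc <- stats::setNames(r$score, r$gene)[rownames(a)]
  for (i in seq_len(nrow(tbl))) {
    expect_equal(tbl$auc[i], oracle_auc(a[, tbl$group[i]], sc))
  }
  expect_true(all(diff(tbl$auc) <= 0))       # sorted descending

  # a group equal to the top genes of a strict ranking scores AUC 1,
  # a bottom group scores 0
  genes <- gene_ids(8)
  strict <- gene_ranking(stats::setNames(8:1, genes))
  a2 <- annot_from_sets(genes, list(top = genes[1:3], bottom = genes[6:8]))
  t2 <- group_multifunctionality(a2, strict)
  expect_equal(t2$auc[t2$group == "top"], 1.0)
  expect_equal(t2$auc[t2$group == "bottom"], 0.0)
})
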