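test_that("neighbor-voting scores rise with training connectivity", {
  genes <- gene_ids(10)
  train <- genes[1:3]
  w <- matrix(0, 10, 10, dimnames = list(genes, genes))
  # g04 connected to every training gene, g05 to none (but to g06)
  w["g04", train] <- w[train, "g04"] <- 1
  w["g05", "g06"] <- w["g06", "g05"] <- 1
  net <- as_network(w)
  sc <- neighbor_voting_scores(net, train)
  expect_gt(sc[["g04"]], sc[["g05"]])

  # empty network: every candidate ties, AUC 0.5 for every group
  empty <- as_network(matrix(0, 10, 10, dimnames = list(genes, genes)))
  a <- random_annotation(10, 4, seed = 2, min_size = 3, max_size = 6)
  ev <- neighbor_voting(empty, a, seed = 1)
  expect_equal(ev$value, rep(0.5, nrow(ev)))
})

test_that("neighbor voting recovers a planted clique and matches the ratio formula", {
  fx <- planted_clique_fixture(n_genes = 60, clique_size = 12,
                               background = 0.02, seed = 3)
  ev <- neighbor_voting(fx$net, fx$annot, folds = 3, seed = 7)
  expect_gte(ev$value, 0.95)

  # brute-force recomputation of the rank-ratio formula for one fold
  train <- fx$members[1:8]
  sc <- neighbor_voting_scores(fx$net, train)
  w <- fx$net$weights
  uni <- rownames(w)
  for (cand in setdiff(uni, train)[1:10]) {
    r <- rank(w[cand, setdiff(uni, cand)], ties.method = "average")
    num <- sum(r[train])
    den <- sum(r[setdiff(names(r), train)])
    expect_equal(sc[[cand]], num / den)
  }
})

test_that("neighbor-voting scores are equivariant under gene relabeling", {
  set.seed(4)
  fx <- planted_clique_fixture(n_genes = 40, clique_size = 8,
                               background = 0.05, seed = 4)
  genes <- rownames(fx$net$weights)
  relabel <- stats::setNames(sprintf("x%02d", sample(40)), genes)
  w2 <- fx$net$weights
  dimnames(w2) <- list(unname(relabel[genes]), unname(relabel[genes]))
  ord <- order(rownames(w2))
  net2 <- as_network(w2[ord, ord])
  train <- fx$members[1:5]
  sc1 <- neighbor_voting_scores(fx$net, train)
  sc2 <- neighbor_voting_scores(net2, unname(relabel[train]))
  expect_equal(unname(sc2[relabel[names(sc1)]]), unname(sc1),
               tolerance = 1e-12)
})

test_that("fixed-ranking evaluation uses one order for every group", {
  genes <- gene_ids(8)
  r <- gene_ranking(stats::setNames(8:1, genes))
  a <- annotation_matrix(matrix(genes %in% genes[1], ncol = 1,
                                dimnames = list(genes, "top")))
  expect_equal(evaluate_fixed_ranking(r, a)$value, 1.0)

  # a random ranking scores at chance on average
  set.seed(9)
  a2 <- random_annotation(50, 20, seed = 9, min_size = 5, max_size = 25)
  means <- replicate(300, {
    rr <- gene_ranking(stats::setNames(sample(50), rownames(a2)))
    mean(evaluate_fixed_ranking(rr, a2)$value)
  })
  expect_equal(mean(means), 0.5, tolerance = 0.02)

  expect_error(
    evaluate_fixed_ranking(gene_ranking(c(x = 1)), a2),
    "cover"
  )
})

test_that("degree ranking of a degree-designed network matches the MF ranking", {
  # build a network whose degree order is exactly the MF order: gene i gets
  # i edges to a reservoir, so degrees are rank-identical to MF by design
  a <- random_annotation(12, 5, seed = 6, min_size = 2, max_size = 8)
  mf <- multifunctionality_scores(a)
  # weighted outer-product construction: gene i's weighted degree is
  # v_i * (S - v_i) with v the MF midranks, which is strictly increasing in
  # v_i here (every v_i < S / 2), so degrees are rank-identical to MF
  v <- rank(mf$score, ties.method = "average")
  w <- outer(v, v)
  diag(w) <- 0
  dimnames(w) <- list(rownames(a), rownames(a))
  net <- as_network(w)
  deg <- stats::setNames(node_degree(net)$degree, node_degree(net)$gene)
  expect_equal(rank(deg), rank(stats::setNames(mf$score, mf$gene)),
               tolerance = 1e-12)
  ev_deg <- evaluate_fixed_ranking(degree_ranking(net), a)
  ev_mf <- evaluate_fixed_ranking(optimal_ranking_auc(a), a)
  expect_equal(ev_deg$value, ev_mf$value, tolerance = 1e-12)
})

test_that("learnable filter equals a brute-force within-group edge scan", {
  fx <- planted_clique_fixture(n_genes = 30, clique_size = 6,
                               background = 0.03, seed = 12)
  a <- random_annotation(30, 12, seed = 12, min_size = 2, max_size = 10)
  keep <- learnable_filter(fx$net, a)
  manual <- colnames(a)[sapply(colnames(a), function(g) {
    idx <- which(a[, g])
    any(fx$net$weights[idx, idx] != 0)
  })]
  expect_setequal(keep, manual)

  # isolated members are dropped, an internally linked group is kept
  genes <- gene_ids(6)
  w <- matrix(0, 6, 6, dimnames = list(genes, genes))
  w["g01", "g02"] <- w["g02", "g01"] <- 1
  net <- as_network(w)
  m <- cbind(linked = genes %in% c("g01", "g02", "g03"),
             isolated = genes %in% c("g04", "g05"))
  rownames(m) <- genes
  expect_equal(learnable_filter(net, annotation_matrix(m)), "linked")
})

test_that("without planted signal neighbor voting adds nothing over degree", {
  # prevalence-only network, no coupling: both predictors sit at chance
  cfg <- synth_config(n_genes = 600, n_groups = 200, min_size = 10,
                      max_size = 40, mf_skew = 1, rho = 0, sparsity = 0.01,
                      seed = 19)
  a <- generate_annotations(cfg)
  net <- generate_network(cfg)
  nv <- suppressMessages(neighbor_voting(net, a, seed = 1))
  dr <- evaluate_fixed_ranking(degree_ranking(net), a, groups = nv$group)
  expect_lt(abs(mean(nv$value) - mean(dr$value)), 0.02)
})

test_that("with planted modules and uniform degrees the network beats degree", {
  cfg <- synth_config(n_genes = 400, n_groups = 12, min_size = 15,
                      max_size = 15, mf_skew = 0, rho = 0, sparsity = 0.05,
                      seed = 23)
  a <- generate_annotations(cfg)
  cfg$planted_modules <- lapply(colnames(a), function(g)
    list(group = g, density = 1.0, degree_balance = TRUE))
  net <- generate_network(cfg, annotations = a)
  nv <- neighbor_voting(net, a, seed = 1)
  dr <- evaluate_fixed_ranking(degree_ranking(net), a, groups = nv$group)
  expect_gte(mean(nv$value) - mean(dr$value), 0.2)
})
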