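# --- Synthetic data with controlled multifunctionality-degree structure ---

#' Configuration for the synthetic-data generators
#'
#' Defines the study conditions for offline experiments: an annotation
#' matrix whose memberships concentrate on high-propensity genes
#' (`mf_skew`), and a network drawn from the prevalence model in which the
#' probability of an edge is proportional to the product `p_i p_j` of
#' per-gene propensities, with `rho` controlling the rank coupling between
#' those propensities and multifunctionality. Planted modules overwrite
#' within-group pairs with dense "real" signal.
#'
#' @param n_genes Universe size (default 1000).
#' @param n_groups Number of annotation groups (default 100).
#' @param min_size,max_size Group-size bounds; sizes are drawn log-uniformly
#'   between them (defaults 20 and 100).
#' @param mf_skew Concentration of membership propensity (>= 0): per-gene
#'   propensity is proportional to `exp(mf_skew * z)` with `z` standard
#'   normal, so 0 gives exchangeable genes and larger values concentrate
#'   annotations on fewer genes (default 1).
#' @param rho Target rank coupling between network degree propensity and
#'   multifunctionality, in \[0, 1\] (default 0; Gaussian copula on ranks).
#' @param sparsity Expected fraction of gene pairs carrying an edge
#'   (default 0.005).
#' @param propensity_sd Log-scale spread of the network propensities
#'   (default 1).
#' @param planted_modules List of `list(group =, density =, degree_balance =)`
#'   entries: within the named annotation group, pairs are rewired to the
#'   stated density; with `degree_balance = TRUE` the members' background
#'   edge probability is lowered so their expected total degree matches the
#'   non-members' (modules then carry signal without a degree footprint).
#' @param seed Integer seed (mandatory; all generators are pure functions of
#'   the configuration).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_genes = 1000, n_groups = 100, min_size = 20,
                         max_size = 100, mf_skew = 1, rho = 0,
                         sparsity = 0.005, propensity_sd = 1,
                         planted_modules = list(), seed) {
  if (missing(seed)) abort("`seed` is mandatory.")
  if (mf_skew < 0) abort("`mf_skew` must be >= 0.")
  if (rho < 0 || rho > 1) abort("`rho` must be in [0, 1].")
  if (sparsity <= 0 || sparsity >= 1) abort("`sparsity` must be in (0, 1).")
  if (min_size < 1 || min_size > max_size) abort("Bad group-size bounds.")
  if (max_size > n_genes) abort("`max_size` exceeds `n_genes`.")
  structure(list(
    n_genes = n_genes, n_groups = n_groups, min_size = min_size,
    max_size = max_size, mf_skew = mf_skew, rho = rho, sparsity = sparsity,
    propensity_sd = propensity_sd, planted_modules = planted_modules,
    seed = as.integer(seed)
  ), class = "synth_config")
}

synth_gene_ids <- function(n) sprintf("g%04d", seq_len(n))

#' Generate a synthetic annotation matrix
#'
#' Each group's size is drawn log-uniformly within the configured bounds and
#' its members are sampled without replacement with per-gene probabilities
#' proportional to `exp(s_j * z)`, where `z` is a standard-normal propensity
#' per gene and the per-group skew `s_j` is drawn uniformly in
#' `[0, mf_skew]`. With `mf_skew = 0` membership is exchangeable across
#' genes; increasing it concentrates annotations — and hence
#' multifunctionality — on a small set of genes, while the per-group
#' modulation reproduces the heterogeneity of real ontologies in which some
#' groups collect well-studied multifunctional genes and others are highly
#' specific.
#'
#' @param config A [synth_config()].
#' @return An [annotation_matrix()] on genes `g0001 ...`.
#' @export
generate_annotations <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  genes <- synth_gene_ids(config$n_genes)
  z <- rnorm(config$n_genes)
  sizes <- round(exp(runif(config$n_groups, log(config$min_size),
                           log(config$max_size))))
  sizes <- pmin(pmax(sizes, config$min_size), config$max_size)
  # groups differ in how strongly they favour high-propensity genes
  # (uniform modulation of the skew), mirroring the heterogeneity of real
  # ontologies where some groups collect well-studied hub genes and others
  # are specific
  skew_j <- config$mf_skew * runif(config$n_groups)
  m <- matrix(FALSE, config$n_genes, config$n_groups,
              dimnames = list(genes, sprintf("G%03d", seq_len(config$n_groups))))
  for (j in seq_len(config$n_groups)) {
    m[sample.int(config$n_genes, sizes[j], prob = exp(skew_j[j] * z)), j] <- TRUE
  }
  annotation_matrix(m)
}

#' Generate a synthetic prevalence-model network
#'
#' Draws a binary network from the `p_i p_j` edge model: each gene gets a
#' propensity `p_i`, and pair `(i, j)` carries an edge with probability
#' proportional to `p_i p_j`, scaled to hit the configured sparsity in
#' expectation (probabilities are capped at 1 with iterative rescaling).
#' With `rho > 0` the propensities are rank-coupled to the supplied
#' multifunctionality scores through a Gaussian copula, reproducing the
#' degree-multifunctionality correlation that drives prediction bias; with
#' `rho = 0` they are independent noise. Planted modules are applied last
#' and overwrite within-group pairs at the stated density.
#'
#' @param config A [synth_config()].
#' @param mf Optional `mf_scores` tibble (from
#'   [multifunctionality_scores()]); required when `rho > 0`. Must cover
#'   the synthetic universe.
#' @param annotations Optional [annotation_matrix()] providing the member
#'   lists of planted module groups (required if `planted_modules` name
#'   groups).
#' @param exact_count If `TRUE`, draw exactly `floor(sparsity * n_pairs)`
#'   edges (weighted sampling without replacement) instead of independent
#'   Bernoulli pairs.
#' @return A binary `gba_network`.
#' @export
generate_network <- function(config, mf = NULL, annotations = NULL,
                             exact_count = FALSE) {
  stopifnot(inherits(config, "synth_config"))
  if (config$rho > 0 && is.null(mf)) {
    abort("`mf` is required when `rho` > 0.")
  }
  set.seed(config$seed + 1L)
  ngene <- config$n_genes
  genes <- synth_gene_ids(ngene)
  eps <- rnorm(ngene)
  if (config$rho > 0) {
    if (!identical(mf$gene, genes)) {
      abort("`mf` must cover the synthetic universe in order.")
    }
    u <- (rank(mf$score, ties.method = "average") - 0.5) / ngene
    z_mf <- qnorm(u)
    latent <- config$rho * z_mf + sqrt(1 - config$rho^2) * eps
  } else {
    latent <- eps
  }
  p <- exp(config$propensity_sd * latent)
  ut <- upper.tri(matrix(0, ngene, ngene))
  pp <- outer(p, p)[ut]
  n_pairs <- length(pp)
  target <- config$sparsity * n_pairs
  # scale q = c * p_i p_j to the target expected edge count, capping at 1
  q <- pp * (target / sum(pp))
  for (it in 1:20) {
    over <- q >= 1
    if (!any(over)) break
    deficit <- target - sum(over)
    if (deficit <= 0) abort("Unreachable sparsity: propensities too concentrated.")
    q[over] <- 1
    q[!over] <- q[!over] * (deficit / sum(q[!over]))
  }
  if (exact_count) {
    k <- floor(config$sparsity * n_pairs)
    chosen <- sample.int(n_pairs, k, prob = q)
    edge_flag <- logical(n_pairs)
    edge_flag[chosen] <- TRUE
  } else {
    edge_flag <- runif(n_pairs) < q
  }
  w <- matrix(0, ngene, ngene, dimnames = list(genes, genes))
  w[ut][edge_flag] <- 1
  w <- w + t(w)
  if (length(config$planted_modules) > 0) {
    if (is.null(annotations)) {
      abort("`annotations` is required to plant modules by group id.")
    }
    planted_mask <- matrix(FALSE, ngene, ngene)
    for (pm in config$planted_modules) {
      members <- which(annotations[, pm$group])
      s <- length(members)
      block <- matrix(runif(s * s) < pm$density, s, s)
      block <- block & upper.tri(block)
      block <- block | t(block)
      w[members, members] <- block * 1
      planted_mask[members, members] <- TRUE
    }
    # degree balancing second, so overlapping modules keep each other's
    # planted edges: only member-to-outside pairs not inside any planted
    # block are redrawn at the reduced background rate
    for (pm in config$planted_modules) {
      if (!isTRUE(pm$degree_balance)) next
      members <- which(annotations[, pm$group])
      s <- length(members)
      mu <- config$sparsity * (ngene - 1)
      within <- (s - 1) * pm$density
      if (within > mu) {
        warn(sprintf(
          "Module %s: within-module degree %.1f exceeds the background mean %.1f; degrees cannot be fully balanced.",
          pm$group, within, mu
        ))
      }
      p_out <- max(0, (mu - within) / (ngene - s))
      outside <- setdiff(seq_len(ngene), members)
      sub <- matrix(runif(s * length(outside)) < p_out, s, length(outside))
      free <- !planted_mask[members, outside, drop = FALSE]
      cur <- w[members, outside, drop = FALSE]
      cur[free] <- sub[free] * 1
      w[members, outside] <- cur
      w[outside, members] <- t(cur)
    }
  }
  as_network(w, binary = TRUE)
}

#' Generate a latent-factor expression matrix
#'
#' Genes of each module load with weight `lambda` on a module-specific
#' latent factor shared across samples, plus unit Gaussian noise scaled by
#' `sqrt(1 - lambda^2)`; non-module genes are pure noise. At `lambda = 1`
#' within-module correlations approach 1 as samples grow; at `lambda = 0`
#' the modules are invisible to coexpression.
#'
#' @param config A [synth_config()] (supplies universe and seed).
#' @param modules List of character vectors of gene ids (may overlap; a
#'   gene in several modules loads on the sum of their factors, rescaled).
#' @param n_samples Number of samples (default 50).
#' @param lambda Factor loading in \[0, 1\] (default 0.8).
#' @return An [expression_matrix()].
#' @export
generate_expression <- function(config, modules = list(), n_samples = 50,
                                lambda = 0.8) {
  stopifnot(inherits(config, "synth_config"))
  if (lambda < 0 || lambda > 1) abort("`lambda` must be in [0, 1].")
  set.seed(config$seed + 2L)
  genes <- synth_gene_ids(config$n_genes)
  vals <- matrix(rnorm(config$n_genes * n_samples), config$n_genes,
                 n_samples,
                 dimnames = list(genes,
                                 sprintf("s%03d", seq_len(n_samples))))
  loading <- matrix(0, config$n_genes, length(modules))
  for (k in seq_along(modules)) {
    idx <- match(modules[[k]], genes)
    if (anyNA(idx)) abort("Module gene outside the synthetic universe.")
    loading[idx, k] <- 1
  }
  if (length(modules) > 0) {
    factors <- matrix(rnorm(length(modules) * n_samples), length(modules),
                      n_samples)
    shared <- (loading / pmax(sqrt(rowSums(loading^2)), 1)) %*% factors
    in_mod <- rowSums(loading) > 0
    vals[in_mod, ] <- lambda * shared[in_mod, , drop = FALSE] +
      sqrt(1 - lambda^2) * vals[in_mod, , drop = FALSE]
  }
  expression_matrix(vals)
}
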