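# Independent oracles and small fixture builders used across the tests.
# These are written directly from first principles, separately from the
# package implementations they check.

# Weir-Cockerham theta-hat for ONE locus, evaluated scalar-by-scalar from
# the variance-component definitions (a, b, c). `geno_by_group` is a list
# of integer vectors (0/1/2, NA = missing), one per group.
oracle_wc_fst_one <- function(geno_by_group) {
  r <- length(geno_by_group)
  n_i <- p_i <- h_i <- numeric(r)
  for (g in seq_len(r)) {
    x <- geno_by_group[[g]]
    x <- x[!is.na(x)]
    n_i[g] <- length(x)
    p_i[g] <- sum(x) / (2 * length(x))
    h_i[g] <- mean(x == 1L)
  }
  n_bar <- mean(n_i)
  n_c <- (sum(n_i) - sum(n_i^2) / sum(n_i)) / (r - 1)
  p_bar <- sum(n_i * p_i) / sum(n_i)
  s2 <- sum(n_i * (p_i - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- sum(n_i * h_i) / sum(n_i)
  a <- (n_bar / n_c) *
    (s2 - (1 / (n_bar - 1)) * (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 - h_bar / 4))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 - ((2 * n_bar - 1) / (4 * n_bar)) * h_bar)
  cc <- h_bar / 2
  if (a + b + cc == 0) return(NA_real_)
  a / (a + b + cc)
}

# Build a genotype_matrix from a plain matrix of calls in one line.
make_gm <- function(calls, groups, locus_ids = NULL, ids = NULL) {
  calls <- as.matrix(calls)
  if (!is.null(locus_ids)) colnames(calls) <- locus_ids
  if (!is.null(ids)) rownames(calls) <- ids
  genotype_matrix(calls, groups)
}

# Monte-Carlo estimate of P[|A intersect B| >= obs] when A, B are uniform
# random subsets of sizes n1, n2 from L loci. Returns the estimate and its
# standard error.
mc_overlap_p <- function(n1, n2, L, obs, n_draws = 10000) {
  hits <- 0L
  for (i in seq_len(n_draws)) {
    a <- sample.int(L, n1)
    b <- sample.int(L, n2)
    if (length(intersect(a, b)) >= obs) hits <- hits + 1L
  }
  p <- hits / n_draws
  list(p = p, se = sqrt(p * (1 - p) / n_draws))
}

# Random additive distance matrix: random topology + uniform branch
# lengths, distances read off the tree path metric.
random_additive_dist <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, rooted = FALSE)
  tr$edge.length <- stats::runif(length(tr$edge.length), 0.1, 2)
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}

# Reduced-chain MCMC settings shared by the simulation-based tests.
fast_cfg <- function(seed = NULL, prior_odds = 10) {
  mcmc_config(profile = "fast", prior_odds_neutral = prior_odds, seed = seed)
}
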