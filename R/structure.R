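#' Genomic relatedness matrix
#'
#' Allele-frequency-standardized (VanRaden) relatedness:
#' `G = Z Z' / (2 * sum_k p_k (1 - p_k))` where `Z` holds genotypes
#' centered by twice the sample allele frequency. Missing genotypes
#' contribute 0 after centering (mean imputation). Monomorphic loci carry
#' no information and are excluded.
#'
#' @param gm a [genotype_matrix()].
#' @return symmetric numeric matrix, individuals x individuals, with
#'   individual ids as dimnames.
#' @export
grm <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (nrow(gm$calls) < 2L) stop("need at least two individuals")
  if (any(rowSums(!is.na(gm$calls)) == 0L)) {
    stop("individual with no called genotypes")
  }
  p <- allele_freq(gm)
  poly <- !is.nan(p) & p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic loci")
  calls <- gm$calls[, poly, drop = FALSE]
  p <- p[poly]
  Z <- sweep(calls, 2L, 2 * p)
  Z[is.na(Z)] <- 0
  denom <- 2 * sum(p * (1 - p))
  G <- tcrossprod(Z) / denom
  dimnames(G) <- list(rownames(gm$calls), rownames(gm$calls))
  (G + t(G)) / 2
}

#' Squared-Euclidean distances induced by a relatedness matrix
#'
#' `d(x, y) = G_xx + G_yy - 2 G_xy`, the squared distance between
#' standardized genotype vectors; small negative values from rounding are
#' clamped to zero.
#'
#' @param G symmetric relatedness matrix, e.g. from [grm()].
#' @return symmetric nonnegative distance matrix.
#' @export
grm_dist <- function(G) {
  G <- as.matrix(G)
  d <- outer(diag(G), diag(G), "+") - 2 * G
  d[d < 0] <- 0
  diag(d) <- 0
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via the standard Q-criterion
#' implementation in \pkg{ape}), returned as newick text. Negative branch
#' lengths, which NJ can produce on non-additive inputs, are clamped to
#' zero with the deficit transferred to the sister branch so path lengths
#' through the parent node are preserved.
#'
#' @param d symmetric nonnegative distance matrix with row/column names,
#'   at least 3 taxa.
#' @param tol asymmetry tolerance.
#' @return list with `tree` (an \pkg{ape} `phylo`) and `newick` (character).
#' @export
nj_tree <- function(d, tol = 1e-8) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("neighbor joining needs at least 3 taxa")
  if (max(abs(d - t(d))) > tol * max(1, max(abs(d)))) {
    stop("distance matrix is not symmetric")
  }
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- sprintf("t%d", seq_len(nrow(d)))
  }
  tr <- ape::nj(stats::as.dist(d))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    deficit <- -tr$edge.length[e]
    parent <- tr$edge[e, 1L]
    sib <- which(tr$edge[, 1L] == parent)
    sib <- setdiff(sib, e)
    if (length(sib) > 0) {
      tr$edge.length[sib[1L]] <- tr$edge.length[sib[1L]] + deficit
    }
    tr$edge.length[e] <- 0
  }
  list(tree = tr, newick = ape::write.tree(tr))
}

#' Principal component analysis of a genotype matrix
#'
#' Genotypes are standardized per locus as `(g - 2 p) / sqrt(2 p (1 - p))`
#' with `p` the sample allele frequency; missing calls are imputed to the
#' locus mean (0 after centering) and monomorphic loci are excluded. The
#' decomposition is a truncated SVD of the standardized matrix; eigenvalue
#' `k` is the squared `k`-th singular value, so the eigenvalues sum to the
#' total standardized variance.
#'
#' @param gm a [genotype_matrix()].
#' @param k_max number of score columns to return.
#' @return list of class `"snp_pca"`: `scores` (individuals x `k_max`),
#'   `eigenvalues` (all `min(n, L)` of them, nonincreasing), `loci_used`.
#' @export
snp_pca <- function(gm, k_max = 10) {
  stopifnot(inherits(gm, "genotype_matrix"))
  p <- allele_freq(gm)
  poly <- !is.nan(p) & p > 0 & p < 1
  if (sum(poly) < 2L) stop("need at least two polymorphic loci")
  n <- nrow(gm$calls)
  if (n < 2L) stop("need at least two individuals")
  if (k_max > min(n, sum(poly))) {
    stop("k_max exceeds min(individuals, polymorphic loci)")
  }
  calls <- gm$calls[, poly, drop = FALSE]
  p <- p[poly]
  X <- sweep(calls, 2L, 2 * p)
  X <- sweep(X, 2L, sqrt(2 * p * (1 - p)), "/")
  X[is.na(X)] <- 0
  sv <- svd(X, nu = k_max, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(k_max)], k_max, k_max)
  rownames(scores) <- rownames(gm$calls)
  colnames(scores) <- sprintf("PC%d", seq_len(k_max))
  structure(
    list(
      scores = scores,
      eigenvalues = sv$d^2,
      loci_used = colnames(calls)
    ),
    class = "snp_pca"
  )
}

#' Choose the number of clusters by BIC over k-means fits
#'
#' Runs k-means (25 restarts) on PC scores for `k = 1 .. k_max` and scores
#' each fit with `BIC(k) = n log(WSS_k / n) + k log(n)`; returns the
#' minimizer, with ties broken toward smaller k.
#'
#' @param scores numeric matrix of PC scores, or a [snp_pca()] result.
#' @param k_max largest cluster number to consider.
#' @param nstart k-means restarts.
#' @param seed RNG seed for the k-means initializations (default 1, so the
#'   choice is deterministic).
#' @return list: `k` (the chosen count), `bic` (numeric vector over k).
#' @export
choose_k_bic <- function(scores, k_max = 6, nstart = 25, seed = 1) {
  if (inherits(scores, "snp_pca")) scores <- scores$scores
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (k_max < 1) stop("k_max must be at least 1")
  if (k_max > n) stop("k_max cannot exceed the number of individuals")
  if (!is.null(seed)) {
    rng <- preserve_rng()
    on.exit(restore_rng(rng))
    set.seed(seed)
  }
  bic <- numeric(k_max)
  for (k in seq_len(k_max)) {
    wss <- if (k == 1L) {
      sum(scale(scores, scale = FALSE)^2)
    } else {
      km <- suppressWarnings(stats::kmeans(scores, centers = k, nstart = nstart))
      km$tot.withinss
    }
    # guard log(0) on perfectly clustered data
    bic[k] <- n * log(max(wss, 1e-12) / n) + k * log(n)
  }
  list(k = which.min(bic), bic = bic)
}

#' Scree-plot elbow rule for the number of components
#'
#' An automated Cattell criterion: with eigenvalues sorted nonincreasing,
#' `K` is the largest index `i` whose drop `lambda_i - lambda_{i+1}`
#' exceeds `tau` times the total range `lambda_1 - lambda_last`; at least
#' 1.
#'
#' @param eigenvalues nonincreasing nonnegative numeric vector, length >= 2.
#' @param tau drop threshold as a proportion of the range (default 0.1).
#' @return integer count of retained components.
#' @export
scree_k <- function(eigenvalues, tau = 0.1) {
  ev <- as.numeric(eigenvalues)
  if (length(ev) < 2L) stop("need at least two eigenvalues")
  if (is.unsorted(rev(ev), strictly = FALSE)) {
    if (any(diff(ev) > 1e-8 * max(abs(ev)))) stop("eigenvalues must be nonincreasing")
  }
  drops <- -diff(ev)
  rng <- ev[1L] - ev[length(ev)]
  big <- which(drops > tau * rng)
  if (length(big) == 0L) 1L else max(big)
}

# Save/restore the caller's RNG state so seeded helpers do not perturb it.
preserve_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Permutation test of PC-morph association
#'
#' The computational restatement of "no genome-wide differentiation
#' between morphs": for each retained PC, the point-biserial correlation
#' between scores and a two-level label is computed; the statistic is the
#' maximum |r| over PCs, compared with its permutation distribution under
#' random relabeling.
#'
#' @param pca a [snp_pca()] result (or a score matrix).
#' @param labels two-level per-individual labels.
#' @param n_perm number of permutations (default 200).
#' @param seed RNG seed for the permutations.
#' @return list: `observed` (max |r|), `perm` (permutation values),
#'   `p_value`, `percentile_95`, `separated` (observed above the 95th
#'   permutation percentile).
#' @export
pc_label_assoc <- function(pca, labels, n_perm = 200, seed = 1) {
  scores <- if (inherits(pca, "snp_pca")) pca$scores else as.matrix(pca)
  labels <- factor(labels)
  if (nlevels(labels) != 2L) stop("labels must have exactly two levels")
  y <- as.numeric(labels == levels(labels)[2L])
  max_abs_r <- function(yy) max(abs(suppressWarnings(stats::cor(scores, yy))), na.rm = TRUE)
  obs <- max_abs_r(y)
  if (!is.null(seed)) {
    rng <- preserve_rng()
    on.exit(restore_rng(rng))
    set.seed(seed)
  }
  perm <- vapply(seq_len(n_perm), function(i) max_abs_r(sample(y)), 0)
  q95 <- stats::quantile(perm, 0.95, names = FALSE)
  list(
    observed = obs,
    perm = perm,
    p_value = (1 + sum(perm >= obs)) / (n_perm + 1),
    percentile_95 = q95,
    separated = obs > q95
  )
}
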