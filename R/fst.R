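#' Weir-Cockerham FST per locus
#'
#' The variance-components estimator theta-hat for diploid data: for each
#' locus the among-group (a), among-individual-within-group (b) and
#' within-individual (c) components are formed from per-group sample
#' sizes, allele frequencies and heterozygote fractions, and
#' `theta = a / (a + b + c)`. Loci where the denominator is zero (e.g.
#' monomorphic) return `NA`. Individuals with missing calls at a locus are
#' excluded from that locus only.
#'
#' @param gm a [genotype_matrix()].
#' @param groups optional per-individual labels (defaults to `gm$groups`);
#'   must have at least two levels.
#' @return named numeric vector of per-locus theta-hat.
#' @export
wc_fst <- function(gm, groups = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.null(groups)) groups <- gm$groups
  groups <- factor(groups)
  r <- nlevels(groups)
  if (r < 2L) stop("need at least two groups")
  calls <- gm$calls
  L <- ncol(calls)

  # per-group, per-locus: called individuals, allele freq, het fraction
  n_i <- p_i <- h_i <- matrix(0, r, L)
  for (g in seq_len(r)) {
    sub <- calls[groups == levels(groups)[g], , drop = FALSE]
    called <- colSums(!is.na(sub))
    n_i[g, ] <- called
    p_i[g, ] <- ifelse(called > 0, colSums(sub, na.rm = TRUE) / (2 * called), NA)
    h_i[g, ] <- ifelse(called > 0, colSums(sub == 1L, na.rm = TRUE) / called, NA)
  }

  n_bar <- colMeans(n_i)
  n_sum <- colSums(n_i)
  n_c <- (n_sum - colSums(n_i^2) / n_sum) / (r - 1)
  p_bar <- colSums(n_i * p_i) / n_sum
  s2 <- colSums(n_i * (p_i - rep(p_bar, each = r))^2) / ((r - 1) * n_bar)
  h_bar <- colSums(n_i * h_i) / n_sum

  a <- (n_bar / n_c) *
    (s2 - (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 - h_bar / 4) / (n_bar - 1))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 - (2 * n_bar - 1) / (4 * n_bar) * h_bar)
  cc <- h_bar / 2

  denom <- a + b + cc
  theta <- ifelse(is.finite(denom) & abs(denom) > 0, a / denom, NA_real_)
  theta[n_bar <= 1 | n_c <= 0 | colSums(n_i == 0) > 0] <- NA_real_
  stats::setNames(theta, colnames(calls))
}
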