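#' MCMC settings for the Bayesian FST outlier scan
#'
#' Defaults are the published run settings of the study design this
#' package reproduces: 10,000 output iterations at a thinning interval of
#' 10, a burn-in of 10,000, 20 pilot runs of length 10,000 for proposal
#' tuning, and prior odds of 10 for the neutral (no locus effect) model.
#' The `"fast"` profile shortens every phase for simulation studies and
#' tests.
#'
#' @param n_output retained posterior samples.
#' @param thinning iterations between retained samples.
#' @param burn_in discarded iterations after tuning.
#' @param n_pilot,pilot_length number and length of proposal-tuning pilot
#'   runs; proposal widths are adapted after each pilot toward acceptance
#'   rates in `[0.25, 0.45]`.
#' @param prior_odds_neutral prior odds of the neutral model; the prior
#'   inclusion probability of a locus effect is
#'   `1 / (1 + prior_odds_neutral)`.
#' @param seed RNG seed used by [bayescan_fit()] (optional).
#' @param profile `"full"` (the defaults) or `"fast"`; explicit arguments
#'   override the profile.
#' @return list of class `"mcmc_config"`.
#' @export
mcmc_config <- function(n_output = NULL, thinning = NULL, burn_in = NULL,
                        n_pilot = NULL, pilot_length = NULL,
                        prior_odds_neutral = 10, seed = NULL,
                        profile = c("full", "fast")) {
  profile <- match.arg(profile)
  def <- if (profile == "full") {
    list(n_output = 10000L, thinning = 10L, burn_in = 10000L,
         n_pilot = 20L, pilot_length = 10000L)
  } else {
    list(n_output = 400L, thinning = 2L, burn_in = 300L,
         n_pilot = 3L, pilot_length = 100L)
  }
  cfg <- list(
    n_output = as.integer(n_output %||% def$n_output),
    thinning = as.integer(thinning %||% def$thinning),
    burn_in = as.integer(burn_in %||% def$burn_in),
    n_pilot = as.integer(n_pilot %||% def$n_pilot),
    pilot_length = as.integer(pilot_length %||% def$pilot_length),
    prior_odds_neutral = prior_odds_neutral,
    seed = seed
  )
  stopifnot(
    cfg$n_output >= 1, cfg$thinning >= 1, cfg$burn_in >= 0,
    cfg$n_pilot >= 0, cfg$pilot_length >= 0, cfg$prior_odds_neutral > 0
  )
  class(cfg) <- "mcmc_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bayesian logistic-FST outlier scan by reversible-jump MCMC
#'
#' Fits the hierarchical model in which the alternate-allele count of
#' locus `i` in group `j` is beta-binomial,
#' `a_ij ~ BetaBin(n_ij, theta_ij p_i, theta_ij (1 - p_i))` with
#' `theta_ij = 1/FST_ij - 1` and `logit(FST_ij) = delta_i alpha_i +
#' beta_j`. The locus-specific selection effect `alpha_i` (prior
#' `N(0, 1)`) is switched in and out by a reversible-jump move whose
#' prior inclusion probability is set by the prior odds of the neutral
#' model; group effects `beta_j` have prior `N(-1, 1)` and ancestral
#' frequencies `p_i` are uniform. Missing genotypes are simply absent from
#' the `a_ij`/`n_ij` counts.
#'
#' The per-locus posterior inclusion probability `P_i` is the fraction of
#' retained samples with `delta_i = 1`; q-values are derived from the
#' `P_i` by [qvalues_from_posteriors()].
#'
#' @param gm a [genotype_matrix()] that has passed [filter_loci()] (the
#'   model requires polymorphic loci).
#' @param groups optional two-level labels (defaults to `gm$groups`).
#' @param cfg an [mcmc_config()].
#' @return data frame of class `"outlier_result"`: `locus_id`,
#'   `post_prob`, `alpha_mean`, `fst_g1`, `fst_g2`, `q_value`, with the
#'   chain diagnostics in `attr(, "diagnostics")`, posterior group-effect
#'   means in `attr(, "beta_mean")` and the group level names in
#'   `attr(, "group_levels")`.
#' @export
bayescan_fit <- function(gm, groups = NULL, cfg = mcmc_config()) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(cfg, "mcmc_config"))
  if (is.null(groups)) groups <- gm$groups
  groups <- factor(groups)
  if (nlevels(groups) != 2L) stop("the scan is defined for exactly two groups")
  if (length(groups) != nrow(gm$calls)) stop("one group label per individual required")

  p <- allele_freq(gm)
  if (any(is.nan(p) | p <= 0 | p >= 1)) {
    stop("monomorphic or all-missing loci present; apply filter_loci() first")
  }
  cnt1 <- group_counts_by(gm, groups, levels(groups)[1L])
  cnt2 <- group_counts_by(gm, groups, levels(groups)[2L])
  if (all(cnt1$n < 2L) || all(cnt2$n < 2L)) {
    stop("a group has fewer than two called gene copies at every locus")
  }
  acount <- cbind(cnt1$a, cnt2$a)
  ncount <- cbind(cnt1$n, cnt2$n)
  storage.mode(acount) <- "integer"
  storage.mode(ncount) <- "integer"

  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  fit <- bayescan_mcmc(
    acount, ncount,
    cfg$n_output, cfg$thinning, cfg$burn_in,
    cfg$n_pilot, cfg$pilot_length, cfg$prior_odds_neutral
  )

  res <- data.frame(
    locus_id = colnames(gm$calls),
    post_prob = fit$post_prob,
    alpha_mean = fit$alpha_mean,
    fst_g1 = fit$fst[, 1L],
    fst_g2 = fit$fst[, 2L],
    q_value = qvalues_from_posteriors(fit$post_prob),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  attr(res, "diagnostics") <- fit$diagnostics
  attr(res, "beta_mean") <- fit$beta_mean
  attr(res, "group_levels") <- levels(groups)
  attr(res, "rj_accept_rate") <- fit$rj_accept_rate
  class(res) <- c("outlier_result", "data.frame")
  res
}

group_counts_by <- function(gm, groups, level) {
  sel <- groups == level
  calls <- gm$calls[sel, , drop = FALSE]
  list(n = 2L * colSums(!is.na(calls)), a = colSums(calls, na.rm = TRUE))
}

#' q-values from posterior inclusion probabilities
#'
#' The q-value of locus `i` is the expected false-discovery rate of the
#' outlier list obtained by thresholding at its posterior probability:
#' the mean of `1 - P_j` over all loci `j` with `P_j >= P_i`. Sorting loci
#' by decreasing `P` therefore yields nondecreasing q.
#'
#' @param P numeric vector of posterior probabilities in `[0, 1]`.
#' @return numeric vector of q-values, same order as `P`.
#' @export
qvalues_from_posteriors <- function(P) {
  if (length(P) == 0L) stop("empty posterior-probability vector")
  if (any(is.na(P)) || any(P < 0 | P > 1)) stop("posterior probabilities must lie in [0, 1]")
  o <- order(P, decreasing = TRUE)
  Ps <- P[o]
  cm <- cumsum(1 - Ps) / seq_along(Ps)
  # ties share the q of the last member of their block
  r <- rle(Ps)
  ends <- cumsum(r$lengths)
  qs <- rep(cm[ends], r$lengths)
  q <- numeric(length(P))
  q[o] <- qs
  q
}

#' Principal-component Mahalanobis outlier scan
#'
#' Each standardized SNP is regressed on the first `K` principal-component
#' score vectors; the `K` regression z-statistics per SNP are combined
#' into a robust Mahalanobis distance (minimum-covariance-determinant
#' location/scatter with support fraction 0.75, so outlier loci do not
#' inflate the null scatter). Distances are rescaled by the genomic
#' inflation factor `lambda = median(D^2) / median(chisq_K)` and converted
#' to p-values on `chisq_K`, with Benjamini-Hochberg q-values.
#'
#' @param gm a filtered [genotype_matrix()].
#' @param K number of principal components to regress on (e.g. from
#'   [scree_k()]); must be below the number of individuals.
#' @param seed RNG seed for the subset search of the robust covariance
#'   estimator (default 1 for determinism).
#' @return data frame: `locus_id`, `stat` (rescaled Mahalanobis `D^2`),
#'   `p_value`, `q_value`; the inflation factor is in `attr(, "lambda")`.
#' @export
pcadapt_scan <- function(gm, K, seed = 1) {
  stopifnot(inherits(gm, "genotype_matrix"), K >= 1)
  n <- nrow(gm$calls)
  if (K >= n) stop("K must be smaller than the number of individuals")
  p <- allele_freq(gm)
  poly <- !is.nan(p) & p > 0 & p < 1
  calls <- gm$calls[, poly, drop = FALSE]
  p <- p[poly]
  X <- sweep(calls, 2L, 2 * p)
  X <- sweep(X, 2L, sqrt(2 * p * (1 - p)), "/")
  X[is.na(X)] <- 0
  L <- ncol(X)

  sv <- svd(X, nu = K, nv = 0)
  U <- sv$u[, seq_len(K), drop = FALSE] # orthonormal regressors
  B <- crossprod(U, X)                  # K x L coefficients
  rss <- pmax(colSums(X^2) - colSums(B^2), 0)
  sigma2 <- rss / max(n - K - 1, 1)
  Z <- t(B) / sqrt(pmax(sigma2, 1e-12)) # L x K z-statistics

  if (!is.null(seed)) {
    rng <- preserve_rng()
    on.exit(restore_rng(rng))
    set.seed(seed)
  }
  rob <- MASS::cov.rob(Z, method = "mcd",
                       quantile.used = max(floor(0.75 * L), K + 1))
  d2 <- stats::mahalanobis(Z, rob$center, rob$cov)
  lambda <- stats::median(d2) / stats::qchisq(0.5, df = K)
  stat <- d2 / lambda
  pval <- stats::pchisq(stat, df = K, lower.tail = FALSE)
  out <- data.frame(
    locus_id = colnames(calls),
    stat = stat,
    p_value = pval,
    q_value = stats::p.adjust(pval, method = "BH"),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  attr(out, "lambda") <- lambda
  out
}
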