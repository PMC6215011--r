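#' Build balanced split-half or randomized group designs
#'
#' The replication strategy for unbalanced morph samples: rather than one
#' scan of 34 vs 62, run two balanced scans that both include every
#' minority-class individual but each use a different, disjoint half of
#' the majority class. Any locus genuinely associated with the class
#' should replicate across the two (partially independent) runs. The
#' `randomized` mode builds null designs: pairs of disjoint uniform-random
#' groups that ignore the class labels entirely, sized like the balanced
#' comparisons.
#'
#' @param labels named per-individual group labels (names are individual
#'   ids). Balanced mode requires exactly two label levels.
#' @param mode `"balanced_split"` or `"randomized"`.
#' @param n_random_runs number of randomized designs (default 20).
#' @param random_group_size size of each randomized group (default 34).
#' @param seed RNG seed; randomized run `r` uses `seed + r` so individual
#'   runs are reproducible in isolation.
#' @return list of designs; each is a list with `run_id`,
#'   `individuals_A`, `individuals_B`, `kind`.
#' @export
make_designs <- function(labels, mode = c("balanced_split", "randomized"),
                         n_random_runs = 20, random_group_size = 34,
                         seed = NULL) {
  mode <- match.arg(mode)
  ids <- names(labels)
  if (is.null(ids)) stop("'labels' must be named by individual id")
  labels <- factor(labels)

  if (mode == "balanced_split") {
    if (nlevels(labels) != 2L) stop("balanced split requires exactly two label levels")
    tab <- table(labels)
    minority <- names(tab)[which.min(tab)]
    majority <- names(tab)[which.max(tab)]
    if (min(tab) < 2L) stop("minority class must have at least two individuals")
    if (!is.null(seed)) set.seed(seed)
    maj_ids <- sample(ids[labels == majority])
    half <- floor(length(maj_ids) / 2)
    halves <- list(maj_ids[seq_len(half)], maj_ids[(half + 1):length(maj_ids)])
    min_ids <- ids[labels == minority]
    lapply(1:2, function(r) {
      list(
        run_id = sprintf("balanced_%d", r),
        individuals_A = min_ids,
        individuals_B = sort(halves[[r]]),
        kind = "balanced_split"
      )
    })
  } else {
    n <- length(ids)
    if (2L * random_group_size > n) {
      stop("two disjoint groups of that size exceed the number of individuals")
    }
    lapply(seq_len(n_random_runs), function(r) {
      if (!is.null(seed)) set.seed(seed + r)
      pick <- sample(ids, 2L * random_group_size)
      list(
        run_id = sprintf("random_%02d", r),
        individuals_A = sort(pick[seq_len(random_group_size)]),
        individuals_B = sort(pick[(random_group_size + 1):(2L * random_group_size)]),
        kind = "randomized"
      )
    })
  }
}

#' Run the Bayesian outlier scan over a list of group designs
#'
#' Subsets the genotype matrix to each design's individuals, relabels the
#' two sets `A`/`B`, re-applies the locus filters on the subset (call rate
#' and minor allele frequency can fall below threshold once individuals
#' are dropped) and fits [bayescan_fit()] with identical settings for
#' every run. Loci dropped per run are recorded on each result
#' (`attr(, "dropped_loci")`).
#'
#' @param gm a filtered [genotype_matrix()].
#' @param designs list of designs from [make_designs()].
#' @param cfg an [mcmc_config()]; run `r` is fitted with seed
#'   `cfg$seed + 1000 * r` when `cfg$seed` is set.
#' @param min_call_rate,min_maf per-run re-filter thresholds (defaults
#'   0.5, 0.05).
#' @return named list of `outlier_result` data frames, one per design.
#' @export
run_replicated_scan <- function(gm, designs, cfg = mcmc_config(),
                                min_call_rate = 0.5, min_maf = 0.05) {
  stopifnot(inherits(gm, "genotype_matrix"))
  out <- vector("list", length(designs))
  names(out) <- vapply(designs, `[[`, "", "run_id")
  for (k in seq_along(designs)) {
    d <- designs[[k]]
    all_ids <- c(d$individuals_A, d$individuals_B)
    if (anyDuplicated(all_ids)) stop("design groups overlap: ", d$run_id)
    if (!all(all_ids %in% rownames(gm$calls))) {
      stop("design names individuals absent from the matrix: ", d$run_id)
    }
    sub <- subset_genotypes(gm, individuals = all_ids)
    sub$groups <- factor(rep(c("A", "B"), c(length(d$individuals_A), length(d$individuals_B))))
    subf <- filter_loci(sub, min_call_rate, min_maf, one_per_tag = FALSE)
    if (ncol(subf$calls) == 0L) stop("no loci survive re-filtering in ", d$run_id)
    run_cfg <- cfg
    if (!is.null(cfg$seed)) run_cfg$seed <- cfg$seed + 1000L * k
    res <- bayescan_fit(subf, cfg = run_cfg)
    attr(res, "dropped_loci") <- setdiff(colnames(gm$calls), colnames(subf$calls))
    attr(res, "run_id") <- d$run_id
    attr(res, "kind") <- d$kind
    out[[k]] <- res
  }
  out
}

#' Expected chance overlap of two independent outlier lists
#'
#' If two scans of the same `L` loci flag `n1` and `n2` loci purely at
#' random (independent uniform subsets), the expected number flagged by
#' both is `n1 * n2 / L`.
#'
#' @param n1,n2 outlier counts of the two runs.
#' @param L total loci scanned.
#' @return expected shared count (numeric).
#' @export
expected_overlap <- function(n1, n2, L) {
  stopifnot(L >= 1)
  if (n1 < 0 || n2 < 0 || n1 > L || n2 > L) {
    stop("outlier counts must lie between 0 and L")
  }
  n1 * n2 / L
}

#' Compare outlier lists from two replicate scans
#'
#' For each q-value threshold, reports the two runs' outlier sets and
#' their intersection over the loci retained in both runs. At the loosest
#' threshold the report adds the expected chance overlap
#' ([expected_overlap()]) and an exact hypergeometric upper-tail
#' probability of observing at least the shared count. Two forms of the
#' top-locus coincidence probability are reported: `(1/L)^2`, the chance
#' that a pre-specified locus tops both independent uniform rankings, and
#' `1/L`, the chance that the two top-ranked loci merely coincide.
#'
#' @param res1,res2 `outlier_result` data frames ([bayescan_fit()]).
#' @param thresholds q-value thresholds (default `c(0.2, 0.1, 0.05)`);
#'   outliers are loci with `q_value <=` the threshold.
#' @param L reference locus count for the expectation and the top-locus
#'   probabilities; defaults to the number of loci common to both runs.
#' @return list of class `"overlap_report"`: per-threshold table
#'   (`threshold`, `n1`, `n2`, `shared`), `shared_loci` (list per
#'   threshold), `expected_overlap`, `overlap_p`, `top_locus` (per run),
#'   `top_locus_coincides`, `p_top_prespecified`, `p_top_coincidence`, `L`.
#' @export
overlap_report <- function(res1, res2, thresholds = c(0.2, 0.1, 0.05), L = NULL) {
  # loci without a q-value in a run (dropped by per-run re-filtering) are
  # excluded; intersections are taken over the common retained set
  common <- intersect(res1$locus_id[!is.na(res1$q_value)],
                      res2$locus_id[!is.na(res2$q_value)])
  if (length(common) == 0L) stop("the two runs share no loci")
  r1 <- res1[match(common, res1$locus_id), ]
  r2 <- res2[match(common, res2$locus_id), ]
  if (is.null(L)) L <- length(common)

  sets1 <- lapply(thresholds, function(t) r1$locus_id[r1$q_value <= t])
  sets2 <- lapply(thresholds, function(t) r2$locus_id[r2$q_value <= t])
  shared <- Map(intersect, sets1, sets2)
  tab <- data.frame(
    threshold = thresholds,
    n1 = lengths(sets1),
    n2 = lengths(sets2),
    shared = lengths(shared)
  )

  n1 <- tab$n1[1L]
  n2 <- tab$n2[1L]
  obs <- tab$shared[1L]
  overlap_p <- stats::phyper(obs - 1, n1, L - n1, n2, lower.tail = FALSE)

  top1 <- r1$locus_id[order(r1$q_value, -r1$post_prob)][1L]
  top2 <- r2$locus_id[order(r2$q_value, -r2$post_prob)][1L]
  structure(
    list(
      table = tab,
      shared_loci = stats::setNames(shared, paste0("q", thresholds)),
      expected_overlap = expected_overlap(n1, n2, L),
      overlap_p = overlap_p,
      top_locus = c(run1 = top1, run2 = top2),
      top_locus_coincides = identical(top1, top2),
      p_top_prespecified = (1 / L)^2,
      p_top_coincidence = 1 / L,
      L = L
    ),
    class = "overlap_report"
  )
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("replicate-scan overlap report (L =", x$L, "loci)\n")
  print(x$table, row.names = FALSE)
  cat(sprintf(
    "expected chance overlap at q <= %.2g: %.4f; P[shared >= %d] = %.3g\n",
    x$table$threshold[1L], x$expected_overlap, x$table$shared[1L], x$overlap_p
  ))
  cat(sprintf(
    "top loci: %s / %s (%s); P(pre-specified locus tops both) = %.3g, P(tops coincide) = %.3g\n",
    x$top_locus[1L], x$top_locus[2L],
    if (x$top_locus_coincides) "coincide" else "differ",
    x$p_top_prespecified, x$p_top_coincidence
  ))
  invisible(x)
}

#' Summarize randomized-null scan runs
#'
#' The false-positive yardstick for the replicate scans: across label-free
#' null runs, the mean and maximum number of loci flagged at the q
#' threshold, and the smallest q-value seen anywhere.
#'
#' @param null_results list of `outlier_result` data frames.
#' @param q_threshold flagging threshold (default 0.2).
#' @return list: `mean_count`, `max_count`, `min_q`, `counts` (per run).
#' @export
null_summary <- function(null_results, q_threshold = 0.2) {
  if (length(null_results) == 0L) stop("no null runs supplied")
  counts <- vapply(null_results, function(r) sum(r$q_value <= q_threshold), 0L)
  list(
    mean_count = mean(counts),
    max_count = max(counts),
    min_q = min(vapply(null_results, function(r) min(r$q_value), 0)),
    counts = counts
  )
}
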