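test_that("balanced split-half designs reuse the minority and halve the majority", {
  labels <- stats::setNames(
    rep(c("macropterous", "micropterous"), c(34, 62)),
    sprintf("ind_%03d", 1:96)
  )
  designs <- make_designs(labels, "balanced_split", seed = 51)
  expect_length(designs, 2L)
  for (d in designs) {
    expect_length(d$individuals_A, 34L)
    expect_setequal(d$individuals_A, names(labels)[labels == "macropterous"])
  }
  expect_equal(sort(lengths(lapply(designs, `[[`, "individuals_B"))), c(31L, 31L))
  halves <- lapply(designs, `[[`, "individuals_B")
  expect_length(intersect(halves[[1]], halves[[2]]), 0L)
  expect_setequal(c(halves[[1]], halves[[2]]), names(labels)[labels == "micropterous"])

  # determinism
  expect_identical(designs, make_designs(labels, "balanced_split", seed = 51))
})

test_that("randomized designs draw disjoint label-free groups", {
  labels <- stats::setNames(rep(c("w", "v"), c(34, 62)), sprintf("i%03d", 1:96))
  designs <- make_designs(labels, "randomized", n_random_runs = 20,
                          random_group_size = 34, seed = 52)
  expect_length(designs, 20L)
  for (d in designs) {
    expect_length(d$individuals_A, 34L)
    expect_length(d$individuals_B, 34L)
    expect_length(intersect(d$individuals_A, d$individuals_B), 0L)
  }
  expect_identical(designs,
                   make_designs(labels, "randomized", n_random_runs = 20,
                                random_group_size = 34, seed = 52))
  expect_error(
    make_designs(labels, "randomized", random_group_size = 50, seed = 1),
    "exceed"
  )
})

test_that("expected chance overlap follows n1 n2 / L", {
  expect_equal(round(expected_overlap(17, 14, 6843), 2), 0.03)
  expect_equal(expected_overlap(17, 14, 6843), 17 * 14 / 6843)
  expect_equal(expected_overlap(0, 14, 6843), 0)
  expect_equal(expected_overlap(100, 100, 100), 100)
  # symmetry and monotonicity
  expect_equal(expected_overlap(5, 9, 50), expected_overlap(9, 5, 50))
  expect_lt(expected_overlap(5, 9, 50), expected_overlap(6, 9, 50))
  expect_error(expected_overlap(20, 5, 10), "between 0 and L")
})

fake_result <- function(locus_ids, q, P = 1 - q) {
  structure(
    data.frame(locus_id = locus_ids, post_prob = P, alpha_mean = NA_real_,
               fst_g1 = NA_real_, fst_g2 = NA_real_, q_value = q,
               stringsAsFactors = FALSE),
    class = c("outlier_result", "data.frame")
  )
}

test_that("overlap reports match exact hypergeometric calculations", {
  ids <- sprintf("L%03d", 1:100)
  q1 <- rep(0.9, 100); q1[1:4] <- 0.01     # outliers a,b,c,d
  q2 <- rep(0.9, 100); q2[2:3] <- 0.01; q2[5] <- 0.01 # b,c,e
  rep1 <- fake_result(ids, q1)
  rep2 <- fake_result(ids, q2)
  ov <- overlap_report(rep1, rep2, thresholds = c(0.2, 0.1, 0.05), L = 100)
  expect_setequal(ov$shared_loci$q0.2, ids[2:3])
  # P[X >= 2], X ~ Hypergeom(100 loci, 4 marked, 3 drawn)
  exact <- 1 - stats::dhyper(0, 4, 96, 3) - stats::dhyper(1, 4, 96, 3)
  expect_equal(ov$overlap_p, exact, tolerance = 1e-10)
  # exact enumeration over all choose(100, 3) subsets: 580/161700
  expect_equal(ov$overlap_p, 580 / 161700, tolerance = 1e-12)
  expect_equal(ov$expected_overlap, 4 * 3 / 100)
  expect_equal(ov$p_top_prespecified, 1e-4)
  expect_equal(ov$p_top_coincidence, 1e-2)

  # disjoint outlier sets: nothing shared, unsurprising
  q3 <- rep(0.9, 100); q3[10:12] <- 0.01
  ov2 <- overlap_report(rep1, fake_result(ids, q3), L = 100)
  expect_length(ov2$shared_loci$q0.2, 0L)
  expect_gt(ov2$overlap_p, 0.85)

  # identical results: full self-overlap, coincident top locus
  ov3 <- overlap_report(rep1, rep1, L = 100)
  expect_setequal(ov3$shared_loci$q0.2, ids[1:4])
  expect_true(ov3$top_locus_coincides)

  # loci dropped in one run (NA q) leave the common set entirely
  q4 <- q2
  q4[2] <- NA
  ov4 <- overlap_report(rep1, fake_result(ids, q4))
  expect_equal(ov4$L, 99)
  expect_setequal(ov4$shared_loci$q0.2, ids[3])
})

test_that("hypergeometric overlap probability agrees with Monte-Carlo permutation", {
  set.seed(53)
  for (case in list(c(17, 14, 300, 2), c(5, 9, 50, 2), c(10, 10, 100, 3))) {
    n1 <- case[1]; n2 <- case[2]; L <- case[3]; obs <- case[4]
    exact <- stats::phyper(obs - 1, n1, L - n1, n2, lower.tail = FALSE)
    mc <- mc_overlap_p(n1, n2, L, obs, n_draws = 10000)
    expect_lt(abs(exact - mc$p), 3 * max(mc$se, 1e-4))
  }
})

test_that("null-run summaries aggregate counts and minima", {
  ids <- sprintf("L%d", 1:50)
  mk <- function(n_out, qmin) {
    q <- rep(0.9, 50)
    if (n_out > 0) q[seq_len(n_out)] <- qmin
    fake_result(ids, q)
  }
  res <- list(mk(10, 0.1), mk(12, 0.05), mk(9, 0.026))
  s <- null_summary(res, q_threshold = 0.2)
  expect_equal(s$mean_count, mean(c(10, 12, 9)))
  expect_equal(s$max_count, 12)
  expect_equal(s$min_q, 0.026)

  s0 <- null_summary(list(mk(0, 0.5)), q_threshold = 0.2)
  expect_equal(s0$mean_count, 0)
  expect_equal(s0$max_count, 0)
  expect_equal(s0$min_q, 0.9)

  s1 <- null_summary(list(mk(7, 0.1)))
  expect_equal(s1$mean_count, s1$max_count)
  expect_error(null_summary(list()), "no null runs")
})

test_that("balanced scans recover planted loci while randomized scans do not", {
  sim <- simulate_genotypes(
    sim_params(n_group1 = 24, n_group2 = 40, n_loci = 400, n_assoc = 3,
               p_assoc_g1 = 0.05, p_assoc_g2 = 0.95, missing_rate = 0.1),
    seed = 55
  )
  gmf <- filter_loci(sim$gm)
  labels <- stats::setNames(as.character(gmf$groups), rownames(gmf$calls))
  planted <- intersect(sim$truth$locus_id[sim$truth$is_assoc], colnames(gmf$calls))
  expect_length(planted, 3L)

  balanced <- run_replicated_scan(
    gmf, make_designs(labels, "balanced_split", seed = 56),
    cfg = fast_cfg(seed = 57)
  )
  ov <- overlap_report(balanced[[1]], balanced[[2]], L = ncol(gmf$calls))
  expect_true(all(planted %in% ov$shared_loci$q0.2))

  nulls <- run_replicated_scan(
    gmf,
    make_designs(labels, "randomized", n_random_runs = 3,
                 random_group_size = 24, seed = 58),
    cfg = fast_cfg(seed = 59)
  )
  ranks <- vapply(nulls, function(r) {
    stats::median(match(planted, r$locus_id[order(-r$post_prob)]))
  }, 0)
  expect_gt(stats::median(ranks), 10)

  expect_length(run_replicated_scan(gmf, list(), fast_cfg(seed = 1)), 0L)
})
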