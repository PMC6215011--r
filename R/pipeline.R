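#' Default pipeline configuration
#'
#' Builds the nested configuration list consumed by [run_pipeline()].
#' Every analysis default mirrors the study design the package
#' reproduces: call-rate and MAF filters of 0.5 and 0.05, one SNP per
#' tag, prior odds 10 for the neutral model, two balanced split-half
#' scans, 20 randomized null runs of two disjoint groups of 34, and
#' q-value thresholds 0.2/0.1/0.05. The `"fast"` profile shrinks the
#' simulated matrix and the chains for quick runs; `"full"` uses the
#' full simulated scale (6,843 loci) and the full chain settings.
#'
#' @param profile `"fast"` or `"full"`.
#' @param seed master seed; stage seeds are derived from it.
#' @param out_dir output directory.
#' @return nested configuration list.
#' @export
pipeline_config <- function(profile = c("fast", "full"), seed = 1,
                            out_dir = "wingscan_out") {
  profile <- match.arg(profile)
  fast <- profile == "fast"
  list(
    version = 1L,
    profile = profile,
    seed = as.integer(seed),
    out_dir = out_dir,
    input = list(genepop = NULL, group_labels = NULL, morphometrics = NULL),
    simulation = list(
      enabled = TRUE,
      n_group1 = 34L, n_group2 = 62L,
      n_loci = if (fast) 2000L else 6843L,
      n_assoc = 3L, p_assoc_g1 = 0.05, p_assoc_g2 = 0.95,
      background_fst = 0, maf_low = 0.05, maf_high = 0.95,
      missing_rate = 0.2,
      morphometrics = TRUE
    ),
    filters = list(min_call_rate = 0.5, min_maf = 0.05, one_per_tag = TRUE),
    structure = list(k_max_bic = 6L, n_pcs = 10L, scree_tau = 0.1),
    mcmc = list(profile = if (fast) "fast" else "full", prior_odds_neutral = 10),
    replication = list(n_random_runs = if (fast) 5L else 20L, random_group_size = 34L),
    q_thresholds = c(0.2, 0.1, 0.05)
  )
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages in study order: obtain genotypes (simulate, or
#' read GENEPOP), filter loci, population-structure checks (relatedness,
#' neighbor-joining tree, PCA, BIC cluster count), the PCA outlier scan,
#' the two balanced split-half Bayesian scans, randomized null scans, the
#' overlap report, and (when morphometrics are available) morph
#' classification and the wing-length model. All tables are written as
#' plain text under `cfg$out_dir`, together with a `summary.txt` and a
#' `manifest.json` recording settings and derived stage seeds. Rerunning
#' with an identical configuration reproduces the outputs.
#'
#' @param cfg configuration list from [pipeline_config()], or the path to
#'   a YAML file holding one.
#' @param quiet suppress progress messages.
#' @return (invisibly) a list with the principal in-memory results:
#'   `gm_filtered`, `locus_stats`, `structure`, `pcadapt`, `balanced`
#'   (scan results), `nulls`, `overlap`, `null_summary`, `morph`,
#'   `truth` (when simulated).
#' @export
run_pipeline <- function(cfg = pipeline_config(), quiet = FALSE) {
  if (is.character(cfg)) cfg <- yaml::read_yaml(cfg)
  validate_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  seeds <- list(
    simulate = cfg$seed, morph = cfg$seed + 1L, designs = cfg$seed + 2L,
    scans = cfg$seed + 3L, nulls = cfg$seed + 4L
  )

  truth <- NULL
  morph_tab <- NULL
  if (isTRUE(cfg$simulation$enabled)) {
    say("simulating genotypes (seed %d)", seeds$simulate)
    sp <- sim_params(
      n_group1 = cfg$simulation$n_group1, n_group2 = cfg$simulation$n_group2,
      n_loci = cfg$simulation$n_loci, n_assoc = cfg$simulation$n_assoc,
      p_assoc_g1 = cfg$simulation$p_assoc_g1, p_assoc_g2 = cfg$simulation$p_assoc_g2,
      background_fst = cfg$simulation$background_fst,
      maf_low = cfg$simulation$maf_low, maf_high = cfg$simulation$maf_high,
      missing_rate = cfg$simulation$missing_rate
    )
    sim <- simulate_genotypes(sp, seed = seeds$simulate)
    gm <- sim$gm
    truth <- sim$truth
    write_truth(truth, file.path(cfg$out_dir, "sim_truth.tsv"))
    write_genepop(gm, file.path(cfg$out_dir, "genotypes.genepop"))
    if (isTRUE(cfg$simulation$morphometrics)) {
      morph_tab <- simulate_morphometrics(
        n1 = cfg$simulation$n_group1, n2 = cfg$simulation$n_group2,
        seed = seeds$morph
      )
      write_morphometrics(morph_tab, file.path(cfg$out_dir, "morphometrics.csv"))
    }
  } else {
    say("reading GENEPOP input %s", cfg$input$genepop)
    gm <- read_genepop(cfg$input$genepop, group_labels = cfg$input$group_labels)
    if (!is.null(cfg$input$morphometrics)) {
      morph_tab <- utils::read.csv(cfg$input$morphometrics, stringsAsFactors = FALSE)
    }
  }

  say("filtering %d loci", ncol(gm$calls))
  gmf <- filter_loci(gm, cfg$filters$min_call_rate, cfg$filters$min_maf,
                     cfg$filters$one_per_tag)
  say("%d loci retained", ncol(gmf$calls))
  stats_tab <- locus_summary(gmf)
  utils::write.table(stats_tab, file.path(cfg$out_dir, "locus_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_genepop(gmf, file.path(cfg$out_dir, "genotypes_filtered.genepop"))

  say("population structure")
  G <- grm(gmf)
  utils::write.table(round(G, 6), file.path(cfg$out_dir, "grm.tsv"),
                     sep = "\t", quote = FALSE)
  nj <- nj_tree(grm_dist(G))
  writeLines(nj$newick, file.path(cfg$out_dir, "relatedness_nj.nwk"))
  # full-rank scores: BIC clustering on a truncated score space can chase
  # low-dimensional noise splits
  k_full <- min(nrow(gmf$calls) - 1L, length(snp_pca(gmf, k_max = 1)$eigenvalues))
  pca <- snp_pca(gmf, k_max = k_full)
  n_pcs <- min(cfg$structure$n_pcs, k_full)
  utils::write.table(
    data.frame(individual_id = rownames(pca$scores), group = gmf$groups,
               round(pca$scores[, seq_len(n_pcs), drop = FALSE], 6)),
    file.path(cfg$out_dir, "pca_scores.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  bic <- choose_k_bic(pca$scores, k_max = min(cfg$structure$k_max_bic, nrow(gmf$calls)),
                      seed = cfg$seed)
  K_scree <- scree_k(pca$eigenvalues[seq_len(n_pcs)], tau = cfg$structure$scree_tau)
  say("BIC cluster count %d; scree K = %d", bic$k, K_scree)

  say("PCA outlier scan (K = %d)", K_scree)
  pscan <- pcadapt_scan(gmf, K = K_scree, seed = cfg$seed)

  say("balanced split-half Bayesian scans")
  labels <- stats::setNames(as.character(gmf$groups), rownames(gmf$calls))
  designs <- make_designs(labels, "balanced_split", seed = seeds$designs)
  cfg_mcmc <- mcmc_config(profile = cfg$mcmc$profile,
                          prior_odds_neutral = cfg$mcmc$prior_odds_neutral,
                          seed = seeds$scans)
  balanced <- run_replicated_scan(gmf, designs, cfg_mcmc,
                                  cfg$filters$min_call_rate, cfg$filters$min_maf)

  say("randomized null scans (%d runs)", cfg$replication$n_random_runs)
  null_designs <- make_designs(labels, "randomized",
                               n_random_runs = cfg$replication$n_random_runs,
                               random_group_size = cfg$replication$random_group_size,
                               seed = seeds$designs)
  cfg_null <- cfg_mcmc
  cfg_null$seed <- seeds$nulls
  nulls <- run_replicated_scan(gmf, null_designs, cfg_null,
                               cfg$filters$min_call_rate, cfg$filters$min_maf)

  ov <- overlap_report(balanced[[1L]], balanced[[2L]],
                       thresholds = cfg$q_thresholds, L = ncol(gmf$calls))
  nsum <- null_summary(nulls, q_threshold = cfg$q_thresholds[1L])

  fst <- wc_fst(gmf)
  scan_tab <- data.frame(
    locus_id = colnames(gmf$calls),
    wc_fst = unname(fst),
    post_prob_run1 = balanced[[1L]]$post_prob[match(colnames(gmf$calls), balanced[[1L]]$locus_id)],
    q_bayes_run1 = balanced[[1L]]$q_value[match(colnames(gmf$calls), balanced[[1L]]$locus_id)],
    post_prob_run2 = balanced[[2L]]$post_prob[match(colnames(gmf$calls), balanced[[2L]]$locus_id)],
    q_bayes_run2 = balanced[[2L]]$q_value[match(colnames(gmf$calls), balanced[[2L]]$locus_id)],
    stat_pca = pscan$stat[match(colnames(gmf$calls), pscan$locus_id)],
    p_pca = pscan$p_value[match(colnames(gmf$calls), pscan$locus_id)],
    q_pca = pscan$q_value[match(colnames(gmf$calls), pscan$locus_id)]
  )
  utils::write.table(scan_tab, file.path(cfg$out_dir, "scan_results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  diag_tab <- do.call(rbind, lapply(balanced, function(r) {
    cbind(run_id = attr(r, "run_id"), attr(r, "diagnostics"))
  }))
  utils::write.table(diag_tab, file.path(cfg$out_dir, "chain_diagnostics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_overlap_tsv(ov, nsum, file.path(cfg$out_dir, "replication_report.tsv"))
  jsonlite::write_json(
    lapply(c(designs, null_designs), function(d) d[c("run_id", "kind", "individuals_A", "individuals_B")]),
    file.path(cfg$out_dir, "group_designs.json"),
    auto_unbox = TRUE, pretty = TRUE
  )

  morph_res <- NULL
  if (!is.null(morph_tab)) {
    say("morphometrics")
    morph_res <- list(
      classification = classify_morphs(morph_tab),
      model = NULL
    )
    morph_tab$assigned_class <- morph_res$classification$class_label
    morph_res$model <- wing_model(morph_tab, class_col = "assigned_class")
    utils::write.csv(morph_tab, file.path(cfg$out_dir, "morphometrics_classified.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.table(morph_res$model$coefficients,
                       file.path(cfg$out_dir, "wing_model.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  writeLines(
    pipeline_summary_text(gm, gmf, bic, K_scree, ov, nsum, morph_res, truth),
    file.path(cfg$out_dir, "summary.txt")
  )
  jsonlite::write_json(
    list(config = cfg, stage_seeds = seeds,
         n_loci_input = ncol(gm$calls), n_loci_filtered = ncol(gmf$calls)),
    file.path(cfg$out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )

  invisible(list(
    gm_filtered = gmf, locus_stats = stats_tab,
    structure = list(grm = G, nj = nj, pca = pca, bic = bic, scree_k = K_scree),
    pcadapt = pscan, balanced = balanced, nulls = nulls,
    overlap = ov, null_summary = nsum, morph = morph_res, truth = truth
  ))
}

validate_config <- function(cfg) {
  need <- c("seed", "out_dir", "filters", "mcmc", "replication", "q_thresholds")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stop("config is missing fields: ", paste(miss, collapse = ", "))
  sim_on <- isTRUE(cfg$simulation$enabled)
  has_input <- !is.null(cfg$input$genepop)
  if (sim_on == has_input) {
    stop("exactly one of a GENEPOP input and an enabled simulation block is required")
  }
  thr <- c(cfg$filters$min_call_rate, cfg$filters$min_maf, cfg$q_thresholds)
  if (any(thr < 0 | thr > 1)) stop("thresholds must lie in [0, 1]")
  invisible(TRUE)
}

write_overlap_tsv <- function(ov, nsum, path) {
  tab <- ov$table
  tab$shared_loci <- vapply(ov$shared_loci, paste, "", collapse = ",")
  tab$expected_overlap <- c(ov$expected_overlap, NA, NA)[seq_len(nrow(tab))]
  tab$overlap_p <- c(ov$overlap_p, NA, NA)[seq_len(nrow(tab))]
  tab$top_locus_run1 <- ov$top_locus[1L]
  tab$top_locus_run2 <- ov$top_locus[2L]
  tab$null_mean <- nsum$mean_count
  tab$null_max <- nsum$max_count
  tab$null_min_q <- nsum$min_q
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

pipeline_summary_text <- function(gm, gmf, bic, K_scree, ov, nsum, morph_res, truth) {
  out <- c(
    "wingscan pipeline summary",
    "=========================",
    sprintf("individuals: %d (%s)", nrow(gm$calls),
            paste(sprintf("%s=%d", levels(gm$groups), table(gm$groups)), collapse = ", ")),
    sprintf("loci: %d input, %d after filtering", ncol(gm$calls), ncol(gmf$calls)),
    sprintf("BIC-optimal cluster count: %d", bic$k),
    sprintf("scree-plot K: %d", K_scree),
    "",
    "balanced split-half scans:",
    utils::capture.output(print(ov$table, row.names = FALSE)),
    sprintf("expected chance overlap: %.4f (P[shared >= %d] = %.3g)",
            ov$expected_overlap, ov$table$shared[1L], ov$overlap_p),
    sprintf("top loci: %s / %s (%s)", ov$top_locus[1L], ov$top_locus[2L],
            if (ov$top_locus_coincides) "coincide" else "differ"),
    sprintf("randomized null runs: mean %.1f, max %d outliers at q <= 0.2; min q = %.4g",
            nsum$mean_count, nsum$max_count, nsum$min_q)
  )
  if (!is.null(truth)) {
    planted <- truth$locus_id[truth$is_assoc]
    shared <- ov$shared_loci[[1L]]
    out <- c(out, "",
             sprintf("planted morph-associated loci: %s", paste(planted, collapse = ", ")),
             sprintf("planted loci shared across both balanced runs at q <= 0.2: %d of %d",
                     sum(planted %in% shared), length(planted)))
  }
  if (!is.null(morph_res)) {
    out <- c(out, "",
             sprintf("morphometric dimorphism: %s",
                     if (morph_res$classification$dimorphic) "yes" else "no"),
             utils::capture.output(print(morph_res$classification$class_stats,
                                         row.names = FALSE)))
  }
  out
}
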