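genepop_2x2 <- c(
  "test export",
  "loc1_10",
  "loc2_5",
  "POP",
  "indA ,  001001 001002",
  "indB ,  002002 000000"
)

test_that("GENEPOP parsing recodes to alternate-allele counts", {
  gm <- read_genepop(genepop_2x2)
  expect_equal(dim(gm$calls), c(2L, 2L))
  # allele 002 is the larger observed code at both loci, hence alternate
  expect_equal(unname(gm$calls[1, ]), c(0L, 1L))
  expect_equal(unname(gm$calls[2, 1]), 2L)
  expect_true(is.na(gm$calls[2, 2]))
  expect_equal(rownames(gm$calls), c("indA", "indB"))
  expect_equal(colnames(gm$calls), c("loc1_10", "loc2_5"))
})

test_that("2-digit allele codes and comma-separated locus lines are accepted", {
  txt <- c("t", "l1, l2", "POP", "x ,  0101 0102", "y ,  0202 0000")
  gm <- read_genepop(txt)
  expect_equal(unname(gm$calls[, 1]), c(0L, 2L))
  expect_equal(unname(gm$calls[1, 2]), 1L)
  expect_true(is.na(gm$calls[2, 2]))
})

test_that("malformed GENEPOP inputs are rejected", {
  expect_error(read_genepop(c("t", "l1", "POP", "x ,  001001 001002")), "declared")
  expect_error(
    read_genepop(c("t", "l1", "POP", "x ,  001002", "y ,  003001", "z ,  002003")),
    "two alleles"
  )
  expect_error(read_genepop(c("t", "l1", "POP", "x ,  00100")), "4 or 6 digits")
})

test_that("writing uses the 3-digit dialect and round-trips", {
  gm <- make_gm(
    rbind(c(0L, 1L), c(2L, NA)),
    groups = c("w", "w"),
    locus_ids = c("loc1_10", "loc2_5"), ids = c("indA", "indB")
  )
  path <- withr::local_tempfile(fileext = ".genepop")
  write_genepop(gm, path)
  lines <- readLines(path)
  expect_true(any(grepl("001002", lines)))   # heterozygote = ref + alt
  expect_true(any(grepl("000000", lines)))   # missing

  back <- read_genepop(path)
  expect_identical(back$calls, gm$calls)
  expect_identical(as.character(back$groups), as.character(gm$groups))
})

test_that("round-trip is the identity on a simulated two-group matrix", {
  sim <- simulate_genotypes(sim_params(n_loci = 60, missing_rate = 0.2), seed = 3)
  path <- withr::local_tempfile(fileext = ".genepop")
  write_genepop(sim$gm, path)
  back <- read_genepop(path)
  expect_identical(back$calls, sim$gm$calls)
  expect_identical(back$groups, sim$gm$groups)
})

test_that("empty matrices cannot be written", {
  gm <- make_gm(matrix(0L, 1, 1), groups = "a")
  gm$calls <- gm$calls[, 0, drop = FALSE]
  expect_error(write_genepop(gm, tempfile()), "empty")
})

test_that("call-rate and MAF filters respect their boundaries", {
  # locus 1: called in 47/96 (0.4896 < 0.5) -> removed at the default
  n <- 96
  l1 <- c(rep(1L, 47), rep(NA_integer_, 49))
  l2 <- rep(1L, n)
  gm <- make_gm(cbind(l1, l2), groups = rep(c("a", "b"), each = 48),
                locus_ids = c("1_1", "2_1"))
  expect_equal(colnames(filter_loci(gm, min_maf = 0)$calls), "2_1")

  # MAF 0.049 removed; MAF exactly 0.05 retained (boundary inclusive)
  n <- 500
  make_maf_locus <- function(k) c(rep(1L, k), rep(0L, n - k)) # maf = k/(2n)
  gm2 <- make_gm(cbind(make_maf_locus(49), make_maf_locus(50)),
                 groups = rep(c("a", "b"), each = 250),
                 locus_ids = c("1_1", "2_1"))
  expect_equal(colnames(filter_loci(gm2)$calls), "2_1")
})

test_that("one SNP per tag keeps the lowest position", {
  calls <- matrix(rep(c(0L, 1L, 2L, 1L), 3), ncol = 3)
  gm <- make_gm(calls, groups = c("a", "a", "b", "b"),
                locus_ids = c("7_33", "7_10", "8_2"))
  kept <- filter_loci(gm, min_call_rate = 0, min_maf = 0)
  expect_setequal(colnames(kept$calls), c("7_10", "8_2"))
})

test_that("filtering is idempotent and leaves retained data untouched", {
  sim <- simulate_genotypes(
    sim_params(n_loci = 300, missing_rate = 0.45, maf_low = 0.01, maf_high = 0.99,
               two_per_tag = TRUE),
    seed = 9
  )
  f1 <- filter_loci(sim$gm)
  f2 <- filter_loci(f1)
  expect_identical(f1$calls, f2$calls)
  expect_identical(rownames(f1$calls), rownames(sim$gm$calls))
  expect_identical(f1$calls, sim$gm$calls[, colnames(f1$calls), drop = FALSE])

  # every retained locus satisfies both thresholds
  st <- locus_summary(f1)
  expect_true(all(st$call_rate >= 0.5))
  expect_true(all(st$maf >= 0.05))
  expect_error(filter_loci(sim$gm, min_call_rate = 1.2), "\\[0, 1\\]")
})

test_that("locus summaries match hand calculations", {
  gm <- make_gm(cbind(c(0L, 1L, 2L, 1L), c(0L, 0L, 0L, 0L), c(1L, 1L, 1L, 1L)),
                groups = rep("a", 4), locus_ids = c("1_1", "2_1", "3_1"))
  st <- locus_summary(gm)
  # calls [0,1,2,1]: p = 0.5, ho = 0.5, he = 2*.25*(8/7)
  expect_equal(st$maf[1], 0.5)
  expect_equal(st$ho[1], 0.5)
  expect_equal(st$he[1], 0.5 * 8 / 7, tolerance = 1e-12)
  # all homozygous reference
  expect_equal(st$maf[2], 0)
  expect_equal(st$ho[2], 0)
  expect_equal(st$he[2], 0)
  # all heterozygous
  expect_equal(st$ho[3], 1)
  expect_equal(st$maf[3], 0.5)

  gm$calls[, 2] <- NA_integer_
  expect_error(locus_summary(gm), "zero called")
})
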