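#' Read a GENEPOP genotype file
#'
#' Parses the GENEPOP plain-text dialect commonly exported by RAD-seq
#' pipelines: a title line, locus names (one per line or comma-separated),
#' and `POP`-delimited sample blocks of diploid 2- or 3-digit allele codes.
#' Genotypes are recoded to alternate-allele counts; the alternate allele
#' at a locus is the numerically larger of the (at most two) observed
#' allele codes. All-zero codes (`"0000"` / `"000000"`) are missing.
#'
#' POP blocks become group labels. By default blocks are labelled `pop1`,
#' `pop2`, ...; a title line of the form `groups: a,b` (as written by
#' [write_genepop()]) overrides this, and an explicit `group_labels`
#' argument overrides both.
#'
#' @param path path to a GENEPOP file (or a character vector of its lines).
#' @param group_labels optional per-individual labels, in file order.
#' @return a [genotype_matrix()].
#' @export
read_genepop <- function(path, group_labels = NULL) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 3L) stop("not a GENEPOP file: too few lines")
  title <- lines[1L]

  is_pop <- toupper(lines) == "POP"
  first_pop <- which(is_pop)[1L]
  if (is.na(first_pop) || first_pop < 3L) {
    stop("not a GENEPOP file: no POP line after the locus names")
  }
  locus_lines <- lines[2:(first_pop - 1L)]
  locus_ids <- trimws(unlist(strsplit(locus_lines, ",")))
  locus_ids <- locus_ids[nzchar(locus_ids)]
  L <- length(locus_ids)
  if (anyDuplicated(locus_ids)) stop("duplicate locus names")

  body <- lines[first_pop:length(lines)]
  pop_idx <- cumsum(toupper(body) == "POP")
  sample_lines <- body[toupper(body) != "POP"]
  sample_pop <- pop_idx[toupper(body) != "POP"]
  n <- length(sample_lines)
  if (n == 0L) stop("GENEPOP file contains no samples")

  ids <- character(n)
  # allele codes per individual x locus, two columns of integers
  a1 <- matrix(NA_integer_, n, L)
  a2 <- matrix(NA_integer_, n, L)
  for (k in seq_len(n)) {
    parts <- strsplit(sample_lines[k], ",", fixed = TRUE)[[1L]]
    if (length(parts) < 2L) stop("sample line lacks the 'id ,' separator: ", sample_lines[k])
    ids[k] <- trimws(parts[1L])
    genos <- strsplit(trimws(paste(parts[-1L], collapse = ",")), "[[:space:]]+")[[1L]]
    if (length(genos) != L) {
      stop(sprintf(
        "individual '%s' has %d genotypes but %d loci are declared",
        ids[k], length(genos), L
      ))
    }
    w <- nchar(genos)
    if (any(w != 4L & w != 6L)) {
      stop(sprintf("individual '%s': genotype codes must be 4 or 6 digits", ids[k]))
    }
    half <- w %/% 2L
    a1[k, ] <- suppressWarnings(as.integer(substr(genos, 1L, half)))
    a2[k, ] <- suppressWarnings(as.integer(substr(genos, half + 1L, w)))
    if (anyNA(a1[k, ]) || anyNA(a2[k, ])) {
      stop(sprintf("individual '%s': non-numeric allele code", ids[k]))
    }
  }

  calls <- matrix(NA_integer_, n, L, dimnames = list(ids, locus_ids))
  for (l in seq_len(L)) {
    c1 <- a1[, l]
    c2 <- a2[, l]
    miss <- c1 == 0L | c2 == 0L
    if (any(xor(c1 == 0L, c2 == 0L))) {
      stop(sprintf("locus '%s': half-missing genotype", locus_ids[l]))
    }
    codes <- sort(unique(c(c1[!miss], c2[!miss])))
    if (length(codes) > 2L) {
      stop(sprintf("locus '%s' has more than two alleles", locus_ids[l]))
    }
    if (length(codes) == 0L) next # all missing
    alt <- if (length(codes) == 2L) {
      codes[2L]
    } else if (codes == 1L) NA_integer_ else codes # monomorphic
    cnt <- if (is.na(alt)) rep(0L, n) else (c1 == alt) + (c2 == alt)
    cnt[miss] <- NA_integer_
    calls[, l] <- as.integer(cnt)
  }

  groups <- if (!is.null(group_labels)) {
    if (length(group_labels) != n) stop("group_labels must match the number of samples")
    group_labels
  } else {
    gl <- sprintf("pop%d", sample_pop)
    m <- regmatches(title, regexec("groups:\\s*(.+)$", title))[[1L]]
    if (length(m) == 2L) {
      nm <- trimws(strsplit(m[2L], ",")[[1L]])
      if (length(nm) == max(sample_pop)) gl <- nm[sample_pop]
    }
    gl
  }
  genotype_matrix(calls, groups)
}

#' Write a genotype matrix in GENEPOP format
#'
#' Emits the 3-digit dialect: reference allele `001`, alternate `002`,
#' missing `000000`, one POP block per group level. The title line records
#' the group names (`groups: ...`) so [read_genepop()] can restore them.
#' Individuals are written grouped by label, in level order.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (nrow(gm$calls) == 0L || ncol(gm$calls) == 0L) stop("empty genotype matrix")
  code <- c(`0` = "001001", `1` = "001002", `2` = "002002")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("wingscan GENEPOP export; groups: %s",
                     paste(levels(gm$groups), collapse = ",")), con)
  writeLines(colnames(gm$calls), con)
  for (lev in levels(gm$groups)) {
    writeLines("POP", con)
    for (k in which(gm$groups == lev)) {
      g <- gm$calls[k, ]
      tok <- ifelse(is.na(g), "000000", code[as.character(g)])
      writeLines(paste0(rownames(gm$calls)[k], " ,  ", paste(tok, collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Filter loci on call rate, minor allele frequency and tag membership
#'
#' Applies the post-genotyping locus filters of a GBS pipeline: retain loci
#' genotyped in at least `min_call_rate` of individuals and with minor
#' allele frequency of at least `min_maf` (computed over all individuals
#' jointly, boundary inclusive), and optionally keep only one SNP per RAD
#' tag. The tag is the locus-id prefix before the underscore; the SNP with
#' the smallest position (ties broken lexicographically on the full id) is
#' kept among the loci that survive the other filters.
#'
#' Retained genotype values and individual order are never altered, so the
#' filter is idempotent.
#'
#' @param gm a [genotype_matrix()].
#' @param min_call_rate,min_maf thresholds in `[0, 1]` (defaults 0.5, 0.05).
#' @param one_per_tag keep only the lowest-position SNP per tag (default
#'   `TRUE`).
#' @return the filtered `genotype_matrix`.
#' @export
filter_loci <- function(gm, min_call_rate = 0.5, min_maf = 0.05,
                        one_per_tag = TRUE) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (min_call_rate < 0 || min_call_rate > 1 || min_maf < 0 || min_maf > 1) {
    stop("thresholds must lie in [0, 1]")
  }
  calls <- gm$calls
  call_rate <- colMeans(!is.na(calls))
  p <- allele_freq(gm)
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0
  keep <- call_rate >= min_call_rate & maf >= min_maf

  if (one_per_tag && any(keep)) {
    ids <- colnames(calls)[keep]
    tag <- sub("_.*$", "", ids)
    pos <- suppressWarnings(as.integer(sub("^.*_", "", ids)))
    pos[is.na(pos)] <- .Machine$integer.max
    ord <- order(tag, pos, ids)
    first <- ids[ord][!duplicated(tag[ord])]
    keep <- keep & colnames(calls) %in% first
  }
  subset_genotypes(gm, loci = which(keep))
}

#' Per-locus summary statistics
#'
#' Call rate, minor allele frequency, observed heterozygosity (fraction of
#' heterozygotes among called individuals) and unbiased expected
#' heterozygosity `2 p (1-p) n_c / (n_c - 1)`, with `n_c` the number of
#' called gene copies (the small-sample correction used by Arlequin).
#'
#' @param gm a [genotype_matrix()].
#' @return data frame: `locus_id`, `call_rate`, `maf`, `ho`, `he`.
#' @export
locus_summary <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  calls <- gm$calls
  n_called <- colSums(!is.na(calls))
  if (any(n_called == 0L)) {
    stop("locus with zero called genotypes: ",
         paste(colnames(calls)[n_called == 0L][1:min(3, sum(n_called == 0))],
               collapse = ", "))
  }
  nc <- 2 * n_called
  p <- colSums(calls, na.rm = TRUE) / nc
  he <- 2 * p * (1 - p) * ifelse(nc > 1, nc / (nc - 1), 1)
  data.frame(
    locus_id = colnames(calls),
    call_rate = n_called / nrow(calls),
    maf = pmin(p, 1 - p),
    ho = colSums(calls == 1L, na.rm = TRUE) / n_called,
    he = he,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
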