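#' Construct a genotype matrix
#'
#' The central data container: a diploid biallelic SNP call matrix
#' (individuals in rows, loci in columns) together with a per-individual
#' group label. Calls count copies of the alternate allele (0, 1, 2);
#' missing genotypes are `NA`, never 0.
#'
#' Locus identifiers follow the tag_position convention of RAD-tag
#' pipelines (e.g. `"14459_12"` is position 12 on tag 14459), which the
#' one-SNP-per-tag filter relies on.
#'
#' @param calls integer matrix, individuals x loci, entries in {0, 1, 2, NA}.
#'   Row names are individual ids, column names locus ids; defaults are
#'   generated when absent.
#' @param groups per-individual group labels (factor or character), length
#'   `nrow(calls)`.
#' @return An object of class `"genotype_matrix"`: a list with elements
#'   `calls` (integer matrix) and `groups` (factor).
#' @export
genotype_matrix <- function(calls, groups) {
  calls <- as.matrix(calls)
  if (nrow(calls) < 1L || ncol(calls) < 1L) {
    stop("genotype matrix must have at least one individual and one locus")
  }
  storage.mode(calls) <- "integer"
  bad <- !is.na(calls) & !(calls %in% 0:2)
  if (any(bad)) stop("genotype calls must be 0, 1, 2 or NA")
  if (is.null(rownames(calls))) {
    rownames(calls) <- sprintf("ind_%03d", seq_len(nrow(calls)))
  }
  if (is.null(colnames(calls))) {
    colnames(calls) <- sprintf("%d_1", seq_len(ncol(calls)))
  }
  if (anyDuplicated(colnames(calls))) stop("locus ids must be unique")
  if (anyDuplicated(rownames(calls))) stop("individual ids must be unique")
  if (length(groups) != nrow(calls)) {
    stop("'groups' must have one label per individual")
  }
  obj <- list(calls = calls, groups = factor(groups))
  class(obj) <- "genotype_matrix"
  obj
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "genotype_matrix: %d individuals x %d loci\n",
    nrow(x$calls), ncol(x$calls)
  ))
  tab <- table(x$groups)
  cat("groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("call rate: %.3f\n", mean(!is.na(x$calls))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Subset a genotype matrix
#'
#' @param gm a [genotype_matrix()].
#' @param individuals individual ids or indices to keep (default all).
#' @param loci locus ids or indices to keep (default all).
#' @return a `genotype_matrix` restricted to the requested rows/columns.
#' @export
subset_genotypes <- function(gm, individuals = NULL, loci = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  ind <- if (is.null(individuals)) seq_len(nrow(gm$calls)) else individuals
  if (is.character(ind)) ind <- match(ind, rownames(gm$calls))
  if (anyNA(ind)) stop("unknown individual id in subset")
  loc <- if (is.null(loci)) seq_len(ncol(gm$calls)) else loci
  calls <- gm$calls[ind, loc, drop = FALSE]
  genotype_matrix(calls, droplevels(gm$groups[ind]))
}

#' Alternate-allele frequencies from called gene copies
#'
#' @param gm a [genotype_matrix()].
#' @return numeric vector, one frequency per locus (`NaN` for loci with no
#'   calls).
#' @export
allele_freq <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  n_called <- colSums(!is.na(gm$calls))
  colSums(gm$calls, na.rm = TRUE) / (2 * n_called)
}

# Called gene copies and alternate-allele counts per locus within one group.
# Returns a list(n, a) of integer vectors over loci.
group_counts <- function(gm, which_group) {
  sel <- gm$groups == which_group
  calls <- gm$calls[sel, , drop = FALSE]
  list(
    n = 2L * colSums(!is.na(calls)),
    a = colSums(calls, na.rm = TRUE)
  )
}
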