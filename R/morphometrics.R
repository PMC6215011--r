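#' Classify wing morphotypes from forewing:body ratios
#'
#' Automates the visual macropterous/micropterous sort: a 1-D two-means
#' clustering (25 restarts) of the forewing:body length ratio, with the
#' classification threshold at the midpoint of the two cluster means. The
#' population is declared dimorphic only when the two clusters' ratio
#' ranges are separated and neither cluster is degenerate: a cluster of
#' fewer than `min_cluster` individuals (e.g. a lone outlier in otherwise
#' unimodal data) cannot establish a second morph, and coincident cluster
#' means mean a single effective class.
#'
#' The classification is scale-invariant: it uses only the dimensionless
#' ratio.
#'
#' @param records data frame with `forewing_mm` and `body_mm` columns
#'   (e.g. from [simulate_morphometrics()]).
#' @param min_cluster smallest cluster size that counts as a morph
#'   (default 2).
#' @param seed RNG seed for the k-means restarts (default 1, so the split
#'   is deterministic).
#' @return list: `class_label` (per record, `"macropterous"` for the
#'   high-ratio cluster, `"micropterous"` for the low, `"unassigned"`
#'   never arises from complete inputs), `dimorphic` (flag), `threshold`,
#'   `class_stats` (per-class ratio mean, sd, n, range).
#' @export
classify_morphs <- function(records, min_cluster = 2, seed = 1) {
  stopifnot(is.data.frame(records), nrow(records) >= 2)
  if (any(records$body_mm <= 0)) stop("body lengths must be positive")
  if (any(records$forewing_mm < 0)) stop("forewing lengths must be nonnegative")
  ratio <- records$forewing_mm / records$body_mm

  if (length(unique(ratio)) < 2L) {
    return(list(
      class_label = rep("micropterous", length(ratio)),
      dimorphic = FALSE,
      threshold = NA_real_,
      class_stats = data.frame(
        class = "micropterous", n = length(ratio),
        mean = mean(ratio), sd = stats::sd(ratio),
        min = min(ratio), max = max(ratio)
      )
    ))
  }

  if (!is.null(seed)) {
    rng <- preserve_rng()
    on.exit(restore_rng(rng))
    set.seed(seed)
  }
  km <- suppressWarnings(stats::kmeans(ratio, centers = 2, nstart = 25))
  hi <- which.max(km$centers)
  threshold <- mean(km$centers)
  label <- ifelse(km$cluster == hi, "macropterous", "micropterous")

  by_cls <- split(ratio, label)
  stats_tab <- data.frame(
    class = names(by_cls),
    n = lengths(by_cls),
    mean = vapply(by_cls, mean, 0),
    sd = vapply(by_cls, stats::sd, 0),
    min = vapply(by_cls, min, 0),
    max = vapply(by_cls, max, 0),
    row.names = NULL
  )
  gap_ok <- length(by_cls) == 2L &&
    min(by_cls$macropterous) > max(by_cls$micropterous)
  dimorphic <- gap_ok &&
    all(lengths(by_cls) >= min_cluster) &&
    diff(range(km$centers)) > 0

  list(
    class_label = label,
    dimorphic = dimorphic,
    threshold = threshold,
    class_stats = stats_tab
  )
}

#' Linear model of forewing length
#'
#' Fits the wing-length model used to confirm that the morph
#' classification is not confounded by size, sex or altitude: an
#' ordinary-least-squares Gaussian linear model of forewing length on
#' body length (mm), sex, sampling altitude and the morph class, with
#' two-sided t-tests per coefficient. Constant (rank-deficient) terms are
#' dropped with a warning.
#'
#' @param records data frame with `forewing_mm`, `body_mm`, `sex`,
#'   `altitude_m` and a class column.
#' @param class_col name of the class column (default `"true_class"`; use
#'   the output of [classify_morphs()] for an automated classification).
#' @param altitude_as_factor treat altitude as a sampling-zone factor
#'   instead of continuous metres (default `FALSE`).
#' @return list: `coefficients` (data frame: `term`, `estimate`,
#'   `std_error`, `t`, `p`), `fit` (the `lm` object), `dropped` (terms
#'   removed as constant).
#' @export
wing_model <- function(records, class_col = "true_class",
                       altitude_as_factor = FALSE) {
  stopifnot(is.data.frame(records))
  need <- c("forewing_mm", "body_mm", "sex", "altitude_m", class_col)
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) stop("missing columns: ", paste(missing_cols, collapse = ", "))

  dat <- data.frame(
    forewing_mm = records$forewing_mm,
    body_mm = records$body_mm,
    sex = factor(records$sex),
    altitude_m = if (altitude_as_factor) factor(records$altitude_m) else records$altitude_m,
    class_label = factor(records[[class_col]])
  )
  terms_all <- c("body_mm", "sex", "altitude_m", "class_label")
  constant <- vapply(terms_all, function(t) length(unique(dat[[t]])) < 2L, TRUE)
  dropped <- terms_all[constant]
  if (length(dropped)) {
    warning("dropping constant term(s): ", paste(dropped, collapse = ", "))
  }
  keep <- terms_all[!constant]
  if (length(keep) == 0L) stop("no non-constant predictors")
  if (nrow(dat) <= length(keep) + 1L) stop("more terms than observations")

  fml <- stats::reformulate(keep, response = "forewing_mm")
  fit <- stats::lm(fml, data = dat)
  sm <- summary(fit)$coefficients
  list(
    coefficients = data.frame(
      term = rownames(sm),
      estimate = sm[, 1L],
      std_error = sm[, 2L],
      t = sm[, 3L],
      p = sm[, 4L],
      row.names = NULL
    ),
    fit = fit,
    dropped = dropped
  )
}
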