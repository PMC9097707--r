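## Site filters and coverage normalization applied before differential
## testing, in the fixed order: minimum coverage, median normalization,
## variability (SD) filter.

#' Minimum-coverage filter
#'
#' Keeps sites where every listed sample (all case samples of every
#' generation and the full control pool of the comparison) has at least
#' `min_total` reads.
#'
#' @param mat A [meth_matrix()].
#' @param samples Character vector of samples the requirement applies to
#'   (default: all samples in the matrix). A `comparison_design` may be
#'   given instead.
#' @param min_total Minimum total reads per sample at a site.
#' @return Filtered [meth_matrix()] (warns when empty).
#' @export
filter_min_coverage <- function(mat, samples = mat$samples, min_total = 5) {
  if (inherits(samples, "comparison_design")) samples <- design_samples(samples)
  ci <- match(samples, mat$samples)
  if (anyNA(ci)) stop("unknown sample(s) in filter")
  keep <- rowSums(mat$total[, ci, drop = FALSE] >= min_total) == length(ci)
  if (!any(keep)) warning("no sites pass the minimum-coverage filter")
  subset_matrix(mat, sites = keep)
}

#' Median-coverage normalization
#'
#' Scales each sample's counts by `median(sample medians) / median_i`, where
#' per-sample medians are taken over sites with at least one read. Counts
#' are rounded half-up to integers and methylated counts capped at totals.
#'
#' @param mat A [meth_matrix()].
#' @param samples Samples to normalize (default all; others pass through
#'   unchanged).
#' @return Normalized [meth_matrix()].
#' @export
normalize_median_coverage <- function(mat, samples = mat$samples) {
  if (inherits(samples, "comparison_design")) samples <- design_samples(samples)
  ci <- match(samples, mat$samples)
  if (anyNA(ci)) stop("unknown sample(s) in normalization")
  meds <- vapply(ci, function(j) {
    x <- mat$total[, j]; x <- x[x > 0]
    if (length(x) == 0) NA_real_ else stats::median(x)
  }, 0)
  if (anyNA(meds))
    stop("sample(s) with all-zero coverage cannot be normalized: ",
         paste(samples[is.na(meds)], collapse = ", "))
  ref <- stats::median(meds)
  fac <- ref / meds
  meth <- mat$meth; total <- mat$total
  round_half_up <- function(x) as.integer(floor(x + 0.5))
  for (k in seq_along(ci)) {
    j <- ci[k]
    tot <- round_half_up(mat$total[, j] * fac[k])
    met <- pmin(round_half_up(mat$meth[, j] * fac[k]), tot)
    total[, j] <- tot; meth[, j] <- met
  }
  out <- meth_matrix(mat$sites, meth, total, samples = mat$samples)
  attr(out, "scaling_factors") <- stats::setNames(fac, samples)
  out
}

#' Variability (standard-deviation) filter
#'
#' Keeps sites whose sample standard deviation of percent methylation
#' (100 * methylated / total) across the given samples is at least `sd_min`
#' percentage points (inclusive). Samples are the cases plus controls of one
#' case-vs-control comparison; totals must be positive (guaranteed after the
#' minimum-coverage filter).
#'
#' @param mat A [meth_matrix()].
#' @param samples Samples over which the SD is computed.
#' @param sd_min Threshold in percentage points.
#' @return Filtered [meth_matrix()].
#' @export
filter_variability <- function(mat, samples = mat$samples, sd_min = 0.5) {
  if (inherits(samples, "comparison_design")) samples <- design_samples(samples)
  ci <- match(samples, mat$samples)
  if (anyNA(ci)) stop("unknown sample(s) in filter")
  pct <- 100 * mat$meth[, ci, drop = FALSE] / pmax(mat$total[, ci, drop = FALSE], 1L)
  mu <- rowMeans(pct)
  sdv <- sqrt(rowSums((pct - mu)^2) / (length(ci) - 1))
  subset_matrix(mat, sites = sdv >= sd_min)
}
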