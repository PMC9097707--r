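#' Per-sample global percentage of methylated CpGs
#'
#' A site is called methylated in a sample iff it has at least one read and
#' the methylated fraction is >= `min_fraction`. The percentage is relative
#' to all CpGs in the matrix (the genome-wide CpG set of the run), not to
#' covered sites only.
#'
#' @param mat A [meth_matrix()].
#' @param min_fraction Call threshold on the methylated read fraction.
#' @return Named numeric vector, percent per sample.
#' @export
call_methylated_sites <- function(mat, min_fraction = 0.5) {
  if (nrow(mat$sites) == 0) stop("empty matrix")
  frac <- mat$meth / pmax(mat$total, 1L)
  called <- mat$total >= 1L & frac >= min_fraction
  stats::setNames(100 * colMeans(called), mat$samples)
}

#' Sample-level quality control
#'
#' Flags samples with mean coverage below `min_mean_coverage`, median
#' coverage over covered sites (total >= 1) below `min_median_coverage`, or a
#' global methylated-CpG percentage above the given percentile of the
#' remaining (coverage-passing) samples. Exclusion is advisory: the report
#' records flags, the caller decides.
#'
#' @param mat A [meth_matrix()].
#' @param sheet Optional sample sheet merged into the report.
#' @param min_mean_coverage,min_median_coverage Coverage thresholds (reads).
#' @param meth_percentile Upper percentile (0-1) for the global-methylation
#'   outlier rule.
#' @return data.frame `qc_report`: per sample mean/median coverage, global
#'   percent methylated, individual flags and a combined `flagged` column.
#' @export
qc_samples <- function(mat, sheet = NULL, min_mean_coverage = 1,
                       min_median_coverage = 5, meth_percentile = 0.97) {
  if (nrow(mat$sites) == 0) stop("empty matrix")
  mean_cov <- colMeans(mat$total)
  med_cov <- apply(mat$total, 2, function(x) {
    x <- x[x >= 1]
    if (length(x) == 0) 0 else stats::median(x)
  })
  pct_meth <- call_methylated_sites(mat)
  low_cov <- mean_cov < min_mean_coverage | med_cov < min_median_coverage
  ref <- pct_meth[!low_cov]
  cutoff <- if (length(ref)) stats::quantile(ref, meth_percentile, names = FALSE)
            else Inf
  high_meth <- pct_meth > cutoff
  rep <- data.frame(sample_id = mat$samples, mean_coverage = unname(mean_cov),
                    median_coverage = unname(med_cov),
                    pct_methylated = unname(pct_meth),
                    flag_low_coverage = unname(low_cov),
                    flag_high_methylation = unname(high_meth),
                    flagged = unname(low_cov | high_meth), row.names = NULL)
  if (!is.null(sheet))
    rep <- merge(rep, sheet, by = "sample_id", sort = FALSE)
  attr(rep, "meth_cutoff") <- cutoff
  rep
}
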